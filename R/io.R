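#' Read a GMT gene-set file
#'
#' GMT is the tab-delimited gene-set exchange format: one set per line with
#' a set name, a free-text description, and then one gene per column.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors of gene identifiers. Set
#'   descriptions are kept in the `"description"` attribute (named character
#'   vector parallel to the list).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- setNames(vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions (recycled
#'   from the `"description"` attribute of `sets`, or `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyNA(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named")
  if (is.null(descriptions)) descriptions <- attr(sets, "description")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- mapply(function(nm, ds, genes) {
    paste(c(nm, ds, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write all synthetic pipeline inputs to a directory
#'
#' Serializes a [simulate_dataset()] result as the plain-text formats the
#' pipeline consumes: one GWAS TSV per study, an eQTL TSV, an LD TSV, a GMT
#' of gene sets, one edge-list TSV per network, and the ground truth as JSON.
#'
#' @param sim A list as returned by [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in unique(sim$studies$study_id)) {
    fwrite(sim$studies[sim$studies$study_id == sid, ],
           file.path(dir, paste0("gwas_", sid, ".tsv")), sep = "\t")
  }
  fwrite(sim$catalog, file.path(dir, "eqtl.tsv"), sep = "\t")
  fwrite(sim$ld, file.path(dir, "ld.tsv"), sep = "\t")
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  for (i in seq_along(sim$networks)) {
    g <- sim$networks[[i]]
    el <- igraph::as_data_frame(g, what = "edges")
    names(el) <- c("source", "target")
    fwrite(el, file.path(dir, sprintf("network_%02d.tsv", i)), sep = "\t")
  }
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage_map <- unique(sim$studies[, c("study_id", "stage")])
  fwrite(stage_map, file.path(dir, "stage_map.tsv"), sep = "\t")
  invisible(dir)
}

#' Read GWAS study TSVs from a directory
#'
#' @param dir Directory containing `gwas_*.tsv` files written by
#'   [write_sim_dataset()] (or files of the same layout).
#' @return A single `data.table` with one row per (study, SNP) record.
#' @export
read_gwas_studies <- function(dir) {
  files <- list.files(dir, pattern = "^gwas_.*\\.tsv$", full.names = TRUE)
  if (length(files) == 0L) stop("no gwas_*.tsv files in ", dir)
  rbindlist(lapply(files, fread))
}
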