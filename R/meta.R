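#' Quality-control filter for per-study GWAS summary statistics
#'
#' Applies the standard record-level exclusions — minor allele frequency
#' below 1%, Hardy-Weinberg disequilibrium (p < 1e-4), imputation quality
#' below 50%, call rate below 75% — and then the stage-presence rule: a SNP
#' must survive in at least `stage_min_counts[1]` Stage-1 studies to enter
#' the Stage-1 meta-analysis and at least `stage_min_counts[2]` Stage-2
#' studies for Stage 2. The combined Stage 1+2 analysis covers the union of
#' SNPs passing either stage's presence filter.
#'
#' @param studies `data.table` of per-study records with columns
#'   `study_id`, `stage`, `snp`, `beta`, `se`, `pvalue`, `maf`,
#'   `hwe_pvalue`, `info`, `call_rate`.
#' @param maf_min,hwe_p_min,info_min,call_rate_min Record-level thresholds;
#'   records strictly below a threshold are excluded.
#' @param stage_min_counts Length-2 integer vector: minimum number of
#'   surviving studies per SNP in Stage 1 and Stage 2.
#' @return A list with elements `records` (surviving rows), `stage1_snps`,
#'   `stage2_snps`, `combined_snps`, and `exclusions` (a `data.table` of
#'   `study_id`, `snp`, `reason`; stage-presence exclusions have
#'   `study_id = NA`).
#' @export
qc_filter_snps <- function(studies,
                           maf_min = 0.01, hwe_p_min = 1e-4,
                           info_min = 0.5, call_rate_min = 0.75,
                           stage_min_counts = c(3L, 5L)) {
  studies <- as.data.table(studies)
  required <- c("study_id", "stage", "snp", "beta", "se", "pvalue",
                "maf", "hwe_pvalue", "info", "call_rate")
  absent <- setdiff(required, names(studies))
  if (length(absent) > 0L)
    stop("format error: missing required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)

  fail <- list(
    maf = studies$maf < maf_min,
    hwe = studies$hwe_pvalue < hwe_p_min,
    info = studies$info < info_min,
    call_rate = studies$call_rate < call_rate_min
  )
  excl <- rbindlist(lapply(names(fail), function(r) {
    idx <- which(fail[[r]])
    data.table(study_id = studies$study_id[idx], snp = studies$snp[idx],
               reason = r)
  }))
  keep <- !Reduce(`|`, fail)
  rec <- studies[keep, ]

  count_stage <- function(st) {
    sub <- rec[rec$stage == st, ]
    tab <- sub[, .N, by = snp]
    tab$snp[tab$N >= stage_min_counts[st]]
  }
  stage1 <- count_stage(1L)
  stage2 <- count_stage(2L)
  dropped1 <- setdiff(unique(rec$snp[rec$stage == 1L]), stage1)
  dropped2 <- setdiff(unique(rec$snp[rec$stage == 2L]), stage2)
  presence <- rbindlist(list(
    data.table(study_id = NA_character_, snp = dropped1,
               reason = "stage1_presence"),
    data.table(study_id = NA_character_, snp = dropped2,
               reason = "stage2_presence")
  ))
  list(records = rec,
       stage1_snps = sort(stage1),
       stage2_snps = sort(stage2),
       combined_snps = sort(union(stage1, stage2)),
       exclusions = rbindlist(list(excl, presence)))
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' `beta_meta = sum(w_i * beta_i) / sum(w_i)` with `w_i = 1/se_i^2`,
#' `se_meta = 1/sqrt(sum(w_i))`, and a two-sided normal p-value.
#'
#' @param betas,ses Numeric vectors of per-study effects and standard
#'   errors (all `ses > 0`).
#' @return A list with `beta_meta`, `se_meta`, `pvalue`.
#' @examples
#' fixed_effect_meta(c(1, 3), c(1, 1))  # beta_meta = 2, se_meta = 1/sqrt(2)
#' @export
fixed_effect_meta <- function(betas, ses) {
  if (length(betas) < 1L || length(betas) != length(ses))
    stop("need >= 1 study with matching betas and ses", call. = FALSE)
  if (any(ses <= 0)) stop("all standard errors must be positive",
                          call. = FALSE)
  w <- 1 / ses^2
  beta_meta <- sum(w * betas) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  list(beta_meta = beta_meta, se_meta = se_meta,
       pvalue = 2 * pnorm(-abs(beta_meta / se_meta)))
}

#' Cochran's Q heterogeneity statistics
#'
#' `Q = sum(w_i * (beta_i - beta_FE)^2)` on `df = k - 1`, with the p-value
#' from the chi-squared distribution and `I2 = max(0, (Q - df)/Q)`.
#'
#' @inheritParams fixed_effect_meta
#' @return A list with `Q`, `df`, `p_Q`, `I2`.
#' @export
heterogeneity_stats <- function(betas, ses) {
  k <- length(betas)
  if (k < 2L) stop("heterogeneity requires >= 2 studies", call. = FALSE)
  if (any(ses <= 0)) stop("all standard errors must be positive",
                          call. = FALSE)
  w <- 1 / ses^2
  beta_fe <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - beta_fe)^2)
  df <- k - 1L
  I2 <- if (Q > 0) max(0, (Q - df) / Q) else 0
  list(Q = Q, df = df, p_Q = pchisq(Q, df, lower.tail = FALSE), I2 = I2)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Moment estimator of the between-study variance,
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with fixed-effect
#' weights `w = 1/se^2`; the pooled estimate then uses weights
#' `1/(se_i^2 + tau2)`.
#'
#' @inheritParams fixed_effect_meta
#' @return A list with `beta_meta`, `se_meta`, `pvalue`, `tau2`.
#' @export
random_effects_meta <- function(betas, ses) {
  if (length(betas) < 2L)
    stop("random-effects meta requires >= 2 studies", call. = FALSE)
  het <- heterogeneity_stats(betas, ses)
  w <- 1 / ses^2
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (het$Q - het$df) / denom) else 0
  w2 <- 1 / (ses^2 + tau2)
  beta_meta <- sum(w2 * betas) / sum(w2)
  se_meta <- 1 / sqrt(sum(w2))
  list(beta_meta = beta_meta, se_meta = se_meta,
       pvalue = 2 * pnorm(-abs(beta_meta / se_meta)), tau2 = tau2)
}

# Vectorized per-SNP meta-analysis of one stage. Uses grouped sums only
# (Q via sum w*b^2 - (sum w*b)^2 / sum w), then re-pools the heterogeneous
# subset with DerSimonian-Laird weights.
meta_one_stage <- function(rec, het_gate_p) {
  rec <- copy(as.data.table(rec))
  rec[, w := 1 / se^2]
  rec[, wb := w * beta]
  rec[, wb2 := w * beta^2]
  rec[, w2s := w^2]
  agg <- rec[, .(n_studies = .N, sw = sum(w), swb = sum(wb),
                 swb2 = sum(wb2), sw2 = sum(w2s)), by = snp]
  agg[, beta := swb / sw]
  agg[, se := 1 / sqrt(sw)]
  agg[, q := pmax(0, swb2 - swb^2 / sw)]
  agg[, df := n_studies - 1L]
  agg[n_studies < 2L, q := NA_real_]
  agg[, p_q := pchisq(q, df, lower.tail = FALSE)]
  agg[, i2 := ifelse(q > 0, pmax(0, (q - df) / q), 0)]
  agg[, tau2 := 0]
  agg[, model := "fixed"]
  het <- agg$n_studies >= 2L & !is.na(agg$p_q) & agg$p_q < het_gate_p
  if (any(het)) {
    dl <- agg[het, ]
    dl[, denom := sw - sw2 / sw]
    dl[, tau2 := ifelse(denom > 0, pmax(0, (q - df) / denom), 0)]
    sub <- rec[rec$snp %in% dl$snp, ]
    sub[dl, tau2 := i.tau2, on = "snp"]
    sub[, wr := 1 / (se^2 + tau2)]
    re <- sub[, .(beta = sum(wr * beta) / sum(wr),
                  se = 1 / sqrt(sum(wr))), by = snp]
    agg[re, `:=`(beta = i.beta, se = i.se, model = "random"), on = "snp"]
    agg[dl, tau2 := i.tau2, on = "snp"]
  }
  agg[, pvalue := 2 * pnorm(-abs(beta / se))]
  out <- agg[, .(snp, n_studies, beta, se, pvalue, q, df, p_q, i2, tau2,
                 model)]
  setorder(out, snp)
  out[]
}

#' Stage-wise meta-analysis of QC-filtered GWAS studies
#'
#' Runs the per-SNP meta-analysis for Stage 1, Stage 2, and the combined
#' Stage 1+2 meta-cohort. Each SNP is pooled by the fixed-effect
#' inverse-variance model; SNPs whose Cochran-Q heterogeneity p-value falls
#' below `het_gate_p` are switched to the DerSimonian-Laird random-effects
#' model. Combined-stage coverage is the union of SNPs passing either
#' stage's presence filter.
#'
#' @param qc Output of [qc_filter_snps()] (or a raw study table, which is
#'   then passed through [qc_filter_snps()] with defaults).
#' @param het_gate_p Heterogeneity gate on the Q-test p-value (default
#'   1e-4).
#' @return A named list of three `data.table`s (`stage1`, `stage2`,
#'   `combined`) with columns `snp`, `n_studies`, `beta`, `se`, `pvalue`,
#'   `q`, `df`, `p_q`, `i2`, `tau2`, `model`.
#' @export
run_stage_meta <- function(qc, het_gate_p = 1e-4) {
  if (is.data.frame(qc)) qc <- qc_filter_snps(qc)
  rec <- qc$records
  list(
    stage1 = meta_one_stage(
      rec[rec$stage == 1L & rec$snp %in% qc$stage1_snps, ], het_gate_p),
    stage2 = meta_one_stage(
      rec[rec$stage == 2L & rec$snp %in% qc$stage2_snps, ], het_gate_p),
    combined = meta_one_stage(
      rec[rec$snp %in% qc$combined_snps, ], het_gate_p)
  )
}
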