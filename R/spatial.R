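#' Percent of the genome altered
#'
#' Length fraction of the autosomal profile whose allele-specific state
#' differs from the normal `(1, 1)`.
#'
#' @param profile A `segment_profile`.
#' @return Percentage in `[0, 100]`.
#' @export
pct_genome_altered <- function(profile) {
  len <- profile$end - profile$start
  100 * sum(len[profile$cn1 != 1 | profile$cn2 != 1]) / sum(len)
}

#' Within- versus between-biopsy distance test
#'
#' Two-sided Wilcoxon rank-sum test comparing crypt-crypt evolutionary
#' distances within a biopsy against those between biopsies (exact p for
#' small samples without ties, normal approximation otherwise).
#'
#' @param distance Numeric vector of pairwise distances.
#' @param same_biopsy Logical vector: does the pair share a biopsy?
#' @return List with `statistic`, `p_value`, group sizes.
#' @export
within_vs_between_test <- function(distance, same_biopsy) {
  w <- distance[same_biopsy]
  b <- distance[!same_biopsy]
  if (length(w) < 2 || length(b) < 2)
    stop("need >= 2 pairs in each group")
  ht <- stats::wilcox.test(b, w, alternative = "two.sided")
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_within = length(w), n_between = length(b))
}

#' Correlation of within-biopsy and between-biopsy diversity
#'
#' Squared Pearson correlation (with its two-sided t-test p) between the
#' per-patient mean within-biopsy crypt diversity and the per-patient mean
#' between-biopsy diversity.
#'
#' @param within,between Numeric vectors, one value per patient (>= 3).
#' @return List with `r_squared`, `r`, `p_value`, `n`.
#' @export
diversity_correlation <- function(within, between) {
  if (length(within) != length(between) || length(within) < 3)
    stop("need >= 3 paired patient values")
  if (stats::sd(within) == 0 || stats::sd(between) == 0)
    stop("zero variance in diversity values")
  ht <- stats::cor.test(within, between)
  list(r_squared = unname(ht$estimate)^2, r = unname(ht$estimate),
       p_value = ht$p.value, n = length(within))
}

spearman_rho <- function(x, y) stats::cor(x, y, method = "spearman")

#' Physical versus evolutionary distance within biopsies
#'
#' Per patient: Spearman rank correlation between the physical distance of
#' within-biopsy crypt pairs (baguette-section units) and their evolutionary
#' distance, with a two-sided permutation p-value (exhaustive enumeration
#' when there are few pairs, otherwise `n_perm` seeded random permutations),
#' and Holm (default) or Bonferroni correction across patients.
#'
#' @param pairs data.frame with columns `patient_id`, `physical`,
#'   `evolutionary`.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation draw.
#' @param method Multiple-testing correction passed to [stats::p.adjust()].
#' @return data.frame per patient: `rho`, `p_value`, `p_corrected`.
#' @export
physical_vs_evolutionary <- function(pairs, n_perm = 1e4, seed = 1L,
                                     method = c("holm", "bonferroni")) {
  method <- match.arg(method)
  set.seed(seed)
  pats <- unique(pairs$patient_id)
  res <- lapply(pats, function(pid) {
    d <- pairs[pairs$patient_id == pid, ]
    x <- d$physical; y <- d$evolutionary
    if (length(unique(x)) < 2 || length(unique(y)) < 2)
      stop("constant ranks for patient ", pid)
    obs <- spearman_rho(x, y)
    n <- length(x)
    if (factorial(n) <= n_perm) {
      perms <- permutations_of(n)
      ref <- apply(perms, 1, function(i) spearman_rho(x, y[i]))
    } else {
      ref <- replicate(n_perm, spearman_rho(x, y[sample.int(n)]))
    }
    p <- mean(abs(ref) >= abs(obs) - 1e-12)
    data.frame(patient_id = pid, rho = obs, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_corrected <- stats::p.adjust(out$p_value, method = method)
  out
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Linear model for biopsy-pair evolutionary distance
#'
#' Ordinary least squares (with intercept) for the evolutionary distance
#' between biopsy pairs as a function of progressor status, time point,
#' maximum distance of the pair from the gastro-esophageal junction, and
#' physical distance between the biopsies.
#'
#' @param pairs data.frame with columns `evolutionary_distance`,
#'   `progressor` (logical), `time_point_second` (logical), `max_gej_cm`,
#'   `biopsy_distance_cm`.
#' @return List: `table` (coefficient table: estimate, SE, t, p) and `fit`.
#' @export
gej_regression <- function(pairs) {
  need <- c("evolutionary_distance", "progressor", "time_point_second",
            "max_gej_cm", "biopsy_distance_cm")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ","))
  X <- data.frame(progressor = as.numeric(pairs$progressor),
                  time_point_second = as.numeric(pairs$time_point_second),
                  max_gej_cm = pairs$max_gej_cm,
                  biopsy_distance_cm = pairs$biopsy_distance_cm)
  fit <- stats::lm(pairs$evolutionary_distance ~ ., data = X)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design; aliased predictors: ",
         paste(bad, collapse = ","))
  }
  tab <- as.data.frame(summary(fit)$coefficients)
  names(tab) <- c("estimate", "se", "t_value", "p_value")
  list(table = tab, fit = fit)
}

#' Alterations versus distance from the GEJ
#'
#' Pearson correlation between a crypt's alteration burden (distance from
#' the unaltered ancestral state, breakpoint count, or percent genome
#' altered) and its distance from the gastro-esophageal junction, per
#' patient and pooled across crypts. A negative pooled r means crypts nearer
#' the GEJ carry more alterations.
#'
#' @param records data.frame with columns `patient_id`, `gej_distance_cm`,
#'   `alterations`.
#' @param min_crypts Patients with fewer crypts are skipped with a warning.
#' @return List: `per_patient` data.frame (r, p per patient) and `pooled`
#'   (r, p, n).
#' @export
alterations_vs_gej <- function(records, min_crypts = 3L) {
  pats <- unique(records$patient_id)
  per <- lapply(pats, function(pid) {
    d <- records[records$patient_id == pid, ]
    if (nrow(d) < min_crypts) {
      warning("patient ", pid, ": fewer than ", min_crypts,
              " crypts, skipped")
      return(NULL)
    }
    if (stats::sd(d$gej_distance_cm) == 0 || stats::sd(d$alterations) == 0)
      return(data.frame(patient_id = pid, r = NA_real_, p_value = NA_real_,
                        n = nrow(d)))
    ht <- stats::cor.test(d$gej_distance_cm, d$alterations)
    data.frame(patient_id = pid, r = unname(ht$estimate),
               p_value = ht$p.value, n = nrow(d))
  })
  pooled <- stats::cor.test(records$gej_distance_cm, records$alterations)
  list(per_patient = do.call(rbind, per),
       pooled = list(r = unname(pooled$estimate), p_value = pooled$p.value,
                     n = nrow(records)))
}
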