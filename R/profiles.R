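#' Allele-specific copy-number profile of one sample
#'
#' A `segment_profile` is a data.frame with columns `chrom`, `start`, `end`
#' (bp, 0-based half-open), `cn1`, `cn2` (non-negative integer copies of
#' allele 1 and allele 2), carrying attributes `sample_id` and `phased`.
#' The normal diploid state is `(1, 1)`; total copy number is `cn1 + cn2`.
#'
#' @param segments data.frame with the columns above, in genome order.
#' @param sample_id Sample identifier.
#' @param phased Logical; whether allele labels are consistent across the
#'   patient's samples (see [phase_alleles()]).
#' @return A `segment_profile`.
#' @export
segment_profile <- function(segments, sample_id, phased = FALSE) {
  need <- c("chrom", "start", "end", "cn1", "cn2")
  if (!all(need %in% names(segments)))
    stop("segments must have columns ", paste(need, collapse = ", "))
  segments <- as.data.frame(segments)[, need]
  segments$chrom <- as.character(segments$chrom)
  rownames(segments) <- NULL
  structure(segments, class = c("segment_profile", "data.frame"),
            sample_id = as.character(sample_id), phased = isTRUE(phased))
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("segment_profile '%s' (%s): %d segments\n",
              attr(x, "sample_id"),
              if (attr(x, "phased")) "phased" else "unphased", nrow(x)))
  NextMethod()
}

sample_id_of <- function(profile) attr(profile, "sample_id")
is_phased <- function(profile) isTRUE(attr(profile, "phased"))

#' Validate a profile against a grid
#'
#' Checks the invariants every ingested profile must satisfy: segments sorted
#' and non-overlapping, contiguous coverage of every grid chromosome, segment
#' boundaries exactly on the patient's shared grid, integer copy numbers
#' `>= 0`, and every segment at least `min_len` long.
#'
#' @param profile A `segment_profile`.
#' @param grid A `genome_grid`.
#' @param min_len Minimum detectable lesion size in bp (default 1 Mb).
#' @return Invisibly `TRUE`; otherwise an error naming sample and segment.
#' @export
validate_profile <- function(profile, grid, min_len = 1e6) {
  sid <- sample_id_of(profile)
  fail <- function(i, msg)
    stop(sprintf("sample %s, segment %d: %s", sid, i, msg), call. = FALSE)
  ref <- grid_segments(grid)
  if (nrow(profile) != nrow(ref))
    stop(sprintf("sample %s: %d segments, grid has %d", sid,
                 nrow(profile), nrow(ref)), call. = FALSE)
  for (i in seq_len(nrow(profile))) {
    p <- profile[i, ]
    if (p$chrom != ref$chrom[i] || p$start != ref$start[i] || p$end != ref$end[i])
      fail(i, sprintf("does not match grid segment %s:%d-%d",
                      ref$chrom[i], ref$start[i], ref$end[i]))
    if (p$end - p$start < min_len)
      fail(i, sprintf("shorter than minimum lesion size %g bp", min_len))
    for (cn in c(p$cn1, p$cn2)) {
      if (is.na(cn) || cn < 0 || cn != round(cn))
        fail(i, "copy numbers must be non-negative integers")
    }
  }
  invisible(TRUE)
}

#' Read allele-specific segment profiles
#'
#' Reads a tab-separated table with header
#' `sample  chrom  start  end  cn1  cn2` and returns one validated
#' `segment_profile` per sample, ordered by `sample_id`.
#'
#' @param path Path to the TSV file.
#' @param grid `genome_grid` all profiles must share.
#' @param min_len Minimum segment length in bp.
#' @return Named list of `segment_profile` objects.
#' @export
read_segment_table <- function(path, grid, min_len = 1e6) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(sample = "character",
                                          chrom = "character"))
  need <- c("sample", "chrom", "start", "end", "cn1", "cn2")
  if (!all(need %in% names(tab)))
    stop("segment table must have columns ", paste(need, collapse = ","))
  if (nrow(tab) == 0) return(structure(list(), names = character(0)))
  ids <- sort(unique(tab$sample))
  out <- lapply(ids, function(sid) {
    seg <- tab[tab$sample == sid, c("chrom", "start", "end", "cn1", "cn2")]
    prof <- segment_profile(seg, sid)
    validate_profile(prof, grid, min_len)
    prof
  })
  names(out) <- ids
  out
}

#' Write segment profiles to TSV
#'
#' @param profiles List of `segment_profile`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_segment_table <- function(profiles, path) {
  rows <- lapply(profiles, function(p)
    cbind(sample = sample_id_of(p), as.data.frame(p)))
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the patient / sample sheet
#'
#' The sheet is a CSV holding the patient rows and sample rows of a cohort.
#' Patient columns: `patient_id, progressor, age_at_t1,
#' months_between_timepoints`. Sample columns: `sample_id, patient_id, role`
#' (`crypt` or `biopsy_epithelium`), `time_point` (1 or 2), `biopsy_id`,
#' `baguette_section` (1-4, crypts only), `crypt_slot` (`a`/`b`, crypts
#' only), `gej_distance_cm`, `sampling_age_years`. One file holds both, with
#' a `record` column distinguishing `patient` and `sample` rows.
#'
#' @param path CSV path.
#' @param age_tol Tolerance in years when checking that time-point-2 sampling
#'   ages equal the time-point-1 age plus the inter-timepoint interval.
#' @return List with data.frames `patients` and `samples`.
#' @export
read_sample_sheet <- function(path, age_tol = 0.1) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  if (!"record" %in% names(tab)) stop("sample sheet needs a 'record' column")
  pats <- tab[tab$record == "patient",
              c("patient_id", "progressor", "age_at_t1",
                "months_between_timepoints")]
  pats$progressor <- as.logical(pats$progressor)
  samps <- tab[tab$record == "sample",
               c("sample_id", "patient_id", "role", "time_point", "biopsy_id",
                 "baguette_section", "crypt_slot", "gej_distance_cm",
                 "sampling_age_years")]
  samps$time_point <- as.integer(samps$time_point)
  samps$baguette_section <- as.integer(samps$baguette_section)
  samps$crypt_slot <- as.character(samps$crypt_slot)
  samps$crypt_slot[!is.na(samps$crypt_slot) & samps$crypt_slot == ""] <- NA
  validate_sample_sheet(pats, samps, age_tol = age_tol)
}

#' Validate and cross-reference patient and sample metadata
#'
#' @param patients,samples data.frames as produced by [read_sample_sheet()].
#' @param age_tol Tolerance (years) for sampling-age consistency.
#' @return List with validated `patients` and `samples`.
#' @export
validate_sample_sheet <- function(patients, samples, age_tol = 0.1) {
  if (anyDuplicated(patients$patient_id)) stop("duplicate patient_id")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (any(is.na(patients$age_at_t1)) || any(patients$age_at_t1 <= 0))
    stop("age_at_t1 must be positive")
  if (any(patients$months_between_timepoints < 0))
    stop("months_between_timepoints must be >= 0")
  orphan <- setdiff(samples$patient_id, patients$patient_id)
  if (length(orphan))
    stop("samples reference unknown patients: ", paste(orphan, collapse = ","))
  if (!all(samples$role %in% c("crypt", "biopsy_epithelium")))
    stop("role must be crypt or biopsy_epithelium")
  if (!all(samples$time_point %in% c(1L, 2L)))
    stop("time_point must be 1 or 2")
  if (any(samples$gej_distance_cm < 0, na.rm = TRUE))
    stop("gej_distance_cm must be >= 0")
  is_crypt <- samples$role == "crypt"
  sec <- samples$baguette_section
  slot <- samples$crypt_slot
  slot[!is.na(slot) & slot == ""] <- NA
  if (any(is_crypt & (is.na(sec) | !(sec %in% 1:4))))
    stop("crypt rows need baguette_section in 1..4")
  if (any(is_crypt & (is.na(slot) | !(slot %in% c("a", "b")))))
    stop("crypt rows need crypt_slot 'a' or 'b'")
  if (any(!is_crypt & (!is.na(sec) | !is.na(slot))))
    stop("biopsy_epithelium rows must not carry crypt fields")
  for (i in seq_len(nrow(samples))) {
    p <- patients[patients$patient_id == samples$patient_id[i], ]
    expect <- p$age_at_t1 +
      (samples$time_point[i] - 1L) * p$months_between_timepoints / 12
    if (abs(samples$sampling_age_years[i] - expect) > age_tol)
      stop(sprintf("sample %s: sampling_age_years %.3f inconsistent with patient ages (expected %.3f)",
                   samples$sample_id[i], samples$sampling_age_years[i], expect))
  }
  list(patients = patients, samples = samples)
}

#' Write the patient / sample sheet
#'
#' @param metas List with `patients` and `samples` data.frames.
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_sample_sheet <- function(metas, path) {
  p <- metas$patients
  s <- metas$samples
  pt <- data.frame(record = "patient", patient_id = p$patient_id,
                   progressor = p$progressor, age_at_t1 = p$age_at_t1,
                   months_between_timepoints = p$months_between_timepoints,
                   sample_id = NA, role = NA, time_point = NA, biopsy_id = NA,
                   baguette_section = NA, crypt_slot = NA,
                   gej_distance_cm = NA, sampling_age_years = NA)
  st <- data.frame(record = "sample", patient_id = s$patient_id,
                   progressor = NA, age_at_t1 = NA,
                   months_between_timepoints = NA,
                   sample_id = s$sample_id, role = s$role,
                   time_point = s$time_point, biopsy_id = s$biopsy_id,
                   baguette_section = s$baguette_section,
                   crypt_slot = s$crypt_slot,
                   gej_distance_cm = s$gej_distance_cm,
                   sampling_age_years = s$sampling_age_years)
  utils::write.csv(rbind(pt, st), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}
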