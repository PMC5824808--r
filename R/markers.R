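#' Allele-specific breakpoint markers
#'
#' A breakpoint marker is a (chromosome, boundary position, allele) triple at
#' which an allele's copy number changes. Chromosome start and end act as
#' pseudo-boundaries: a terminal segment whose allele copy number deviates
#' from 1 emits an edge marker, so whole-arm and whole-chromosome events are
#' scoreable. Marker identity deliberately ignores the magnitude of the
#' copy-number change, since markers are used as binary presence/absence
#' phylogenetic characters.
#'
#' @name breakpoint_markers
NULL

marker_id <- function(chrom, pos, allele)
  sprintf("%s:%.0f:a%d", chrom, pos, allele)

profile_marker_table <- function(profile) {
  out <- list()
  for (ch in unique(profile$chrom)) {
    seg <- profile[profile$chrom == ch, ]
    for (allele in 1:2) {
      cn <- seg[[paste0("cn", allele)]]
      # flank with the unaltered state so chromosome ends are boundaries too
      cnx <- c(1L, cn, 1L)
      posx <- c(seg$start[1], seg$end)
      chg <- which(cnx[-1] != cnx[-length(cnx)])
      if (length(chg))
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, pos = posx[chg], allele = allele,
          cn_left = cnx[chg], cn_right = cnx[chg + 1L],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), pos = numeric(0),
                      allele = integer(0), cn_left = integer(0),
                      cn_right = integer(0)))
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$chrom, tab$pos, tab$allele), ]
  rownames(tab) <- NULL
  tab$marker_id <- marker_id(tab$chrom, tab$pos, tab$allele)
  tab
}

#' Extract breakpoint markers from a phased profile
#'
#' @param profile A phased `segment_profile`.
#' @return data.frame with columns `marker_id`, `chrom`, `pos`, `allele`,
#'   `cn_left`, `cn_right`, one row per marker, in genome order.
#' @export
extract_breakpoints <- function(profile) {
  if (!is_phased(profile))
    stop("profile must be phased; run phase_alleles() first")
  profile_marker_table(profile)
}

flip_chromosome <- function(profile, chrom) {
  i <- profile$chrom == chrom
  tmp <- profile$cn1[i]
  profile$cn1[i] <- profile$cn2[i]
  profile$cn2[i] <- tmp
  profile
}

n_altered_segments <- function(profile)
  sum(profile$cn1 != 1 | profile$cn2 != 1)

#' Phase allele labels across a patient's samples
#'
#' Incoming allele-specific profiles carry arbitrary per-chromosome allele
#' labels: "allele 1" in one sample need not be the same haplotype as
#' "allele 1" in another. To decide whether two samples gained or lost the
#' same allele (shared ancestry) or opposite alleles (independent events),
#' labels are made consistent greedily: samples are processed in order of
#' decreasing alteration count (ties broken by sample id), and for each
#' chromosome of each sample the two possible label assignments (keep or
#' flip) are scored by the number of breakpoint markers shared with the
#' already-labelled samples; the higher-scoring assignment wins, ties keep
#' the incoming labels.
#'
#' This is a stand-in for a haplotype-aware phasing procedure; the simulator
#' provides haplotype truth against which its error rate can be measured.
#'
#' @param profiles List of `segment_profile` from one patient (shared grid).
#' @param seed Unused randomness hook, kept for interface stability; the
#'   procedure is fully deterministic.
#' @return List of phased `segment_profile` in the input order.
#' @export
phase_alleles <- function(profiles, seed = 1L) {
  if (!length(profiles)) return(profiles)
  ids <- vapply(profiles, sample_id_of, "")
  nalt <- vapply(profiles, n_altered_segments, 0)
  ord <- order(-nalt, ids)
  chroms <- unique(profiles[[1]]$chrom)
  # votes: how many labelled samples carry each marker; a marker shared by
  # many samples dominates the orientation choice, so one unusual genotype
  # (e.g. both alleles breaking at one boundary) cannot tie the vote
  votes <- integer(0)
  score <- function(mk) sum(votes[mk], na.rm = TRUE)
  phased <- profiles
  for (k in ord) {
    p <- profiles[[k]]
    for (ch in chroms) {
      keep <- profile_marker_table(p)
      keep <- keep$marker_id[keep$chrom == ch]
      pf <- flip_chromosome(p, ch)
      flip <- profile_marker_table(pf)
      flip <- flip$marker_id[flip$chrom == ch]
      if (score(flip) > score(keep)) p <- pf
    }
    mk <- profile_marker_table(p)$marker_id
    new <- setdiff(mk, names(votes))
    votes[new] <- 0L
    votes[mk] <- votes[mk] + 1L
    attr(p, "phased") <- TRUE
    phased[[k]] <- p
  }
  phased
}

#' Build the marker catalog and presence/absence character matrix
#'
#' Takes the union of breakpoint markers over a patient's phased profiles and
#' scores each sample 1 if it carries the marker, 0 if not, and `NA` when the
#' sample's profile has no segments on the marker's chromosome. When
#' `tolerance_bp > 0`, boundaries closer than the tolerance are merged onto
#' one marker (the leftmost position represents the group); profiles on one
#' shared grid never need this.
#'
#' @param profiles List of phased `segment_profile`.
#' @param tolerance_bp Boundary-matching tolerance in bp.
#' @return List with `catalog` (data.frame of markers in (chromosome,
#'   position, allele) order) and `matrix` (samples x markers integer matrix
#'   of 0/1/NA, dimnames set).
#' @export
build_character_matrix <- function(profiles, tolerance_bp = 0) {
  stopifnot(length(profiles) >= 1)
  if (!all(vapply(profiles, is_phased, TRUE)))
    stop("all profiles must be phased")
  ids <- vapply(profiles, sample_id_of, "")
  tabs <- lapply(profiles, profile_marker_table)
  cat_all <- unique(do.call(rbind, lapply(tabs, function(t)
    t[, c("chrom", "pos", "allele")])))
  if (tolerance_bp > 0 && nrow(cat_all)) {
    cat_all <- cat_all[order(cat_all$chrom, cat_all$allele, cat_all$pos), ]
    key <- paste(cat_all$chrom, cat_all$allele)
    snapped <- cat_all$pos
    for (g in unique(key)) {
      i <- which(key == g)
      rep_pos <- cat_all$pos[i[1]]
      for (j in i) {
        if (cat_all$pos[j] - rep_pos > tolerance_bp) rep_pos <- cat_all$pos[j]
        snapped[j] <- rep_pos
      }
    }
    cat_all$pos <- snapped
    cat_all <- unique(cat_all)
  }
  cat_all <- cat_all[order(cat_all$chrom, cat_all$pos, cat_all$allele), ]
  rownames(cat_all) <- NULL
  cat_all$marker_id <- marker_id(cat_all$chrom, cat_all$pos, cat_all$allele)
  m <- matrix(0L, length(profiles), nrow(cat_all),
              dimnames = list(ids, cat_all$marker_id))
  for (s in seq_along(profiles)) {
    t_s <- tabs[[s]]
    if (tolerance_bp > 0 && nrow(t_s)) {
      hit <- logical(nrow(cat_all))
      for (r in seq_len(nrow(t_s))) {
        j <- which(cat_all$chrom == t_s$chrom[r] &
                   cat_all$allele == t_s$allele[r] &
                   abs(cat_all$pos - t_s$pos[r]) <= tolerance_bp)
        if (!length(j))
          stop(sprintf("sample %s: boundary %s:%.0f beyond tolerance",
                       ids[s], t_s$chrom[r], t_s$pos[r]))
        hit[j[1]] <- TRUE
      }
      m[s, hit] <- 1L
    } else {
      m[s, colnames(m) %in% t_s$marker_id] <- 1L
    }
    absent_chrom <- setdiff(cat_all$chrom, unique(profiles[[s]]$chrom))
    if (length(absent_chrom))
      m[s, cat_all$chrom %in% absent_chrom] <- NA
  }
  list(catalog = cat_all, matrix = m)
}

#' Markers present in every sample
#'
#' Detects ubiquitous ("clonal") markers: the exact intersection over
#' samples, treating `NA` conservatively as absence.
#'
#' @param matrix Samples x markers 0/1/NA matrix.
#' @return Character vector of marker ids carried by all samples.
#' @export
clonal_markers <- function(matrix) {
  if (!nrow(matrix) || !ncol(matrix)) return(character(0))
  m <- matrix
  m[is.na(m)] <- 0L
  colnames(m)[colSums(m == 1L) == nrow(m)]
}

#' Crypt-versus-biopsy marker divergence
#'
#' For each crypt, compares its markers with those of the whole-biopsy
#' epithelium it was isolated from: markers private to the crypt, markers
#' missing from the crypt, and the percentage of divergent markers among
#' informative ones (markers present in either sample, both scored non-NA).
#'
#' @param matrix Samples x markers 0/1/NA matrix.
#' @param samples Sample metadata data.frame (see [read_sample_sheet()]).
#' @return data.frame with one row per crypt: `crypt_id`, `biopsy_id`,
#'   `n_private_to_crypt`, `n_missing_from_crypt`, `pct_divergent`,
#'   `zero_informative`.
#' @export
crypt_biopsy_divergence <- function(matrix, samples) {
  crypts <- samples[samples$role == "crypt", ]
  crypts <- crypts[crypts$sample_id %in% rownames(matrix), ]
  out <- lapply(seq_len(nrow(crypts)), function(i) {
    cid <- crypts$sample_id[i]
    bid <- crypts$biopsy_id[i]
    parent <- samples$sample_id[samples$role == "biopsy_epithelium" &
                                samples$biopsy_id == bid &
                                samples$patient_id == crypts$patient_id[i]]
    if (length(parent) != 1 || !(parent %in% rownames(matrix)))
      stop(sprintf("crypt %s: parent biopsy epithelium for %s not in matrix",
                   cid, bid))
    cv <- matrix[cid, ]
    bv <- matrix[parent, ]
    ok <- !is.na(cv) & !is.na(bv)
    private <- sum(cv[ok] == 1 & bv[ok] == 0)
    missing <- sum(cv[ok] == 0 & bv[ok] == 1)
    union_n <- sum(cv[ok] == 1 | bv[ok] == 1)
    data.frame(crypt_id = cid, biopsy_id = bid,
               n_private_to_crypt = private, n_missing_from_crypt = missing,
               pct_divergent = if (union_n) 100 * (private + missing) / union_n else 0,
               zero_informative = union_n == 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

majority_state_in_window <- function(profile, chrom, w0, w1) {
  seg <- profile[profile$chrom == chrom, ]
  ov0 <- pmax(seg$start, w0)
  ov1 <- pmin(seg$end, w1)
  len <- pmax(0, ov1 - ov0)
  keep <- len > 0
  if (!any(keep)) return(NA_integer_)
  tot <- seg$cn1[keep] + seg$cn2[keep]
  agg <- tapply(len[keep], tot, sum)
  states <- as.integer(names(agg))
  states[order(-agg, states)][1]  # majority by length, ties to lower state
}

#' Window-based copy-number distance between two profiles
#'
#' The validation-cohort distance: the genome is tiled into fixed windows
#' from each chromosome start and the two samples are compared window by
#' window on total copy number, each window taking the state covering the
#' majority of its length. The distance is the percentage of windows whose
#' states differ.
#'
#' @param profileA,profileB `segment_profile` objects on the same genome.
#' @param window_bp Window size in bp (default 1 Mb).
#' @return Percentage in `[0, 100]`; symmetric in its arguments.
#' @export
window_distance <- function(profileA, profileB, window_bp = 1e6) {
  chroms <- unique(c(profileA$chrom, profileB$chrom))
  n_tot <- 0L
  n_diff <- 0L
  for (ch in chroms) {
    len <- max(profileA$end[profileA$chrom == ch],
               profileB$end[profileB$chrom == ch])
    starts <- seq(0, len - 1, by = window_bp)
    for (w0 in starts) {
      w1 <- min(w0 + window_bp, len)
      a <- majority_state_in_window(profileA, ch, w0, w1)
      b <- majority_state_in_window(profileB, ch, w0, w1)
      n_tot <- n_tot + 1L
      if (!is.na(a) && !is.na(b) && a != b) n_diff <- n_diff + 1L
    }
  }
  if (!n_tot) return(0)
  100 * n_diff / n_tot
}

#' Export a character matrix as NEXUS
#'
#' STANDARD datatype with symbols "01" and missing character "?" so the
#' matrix can be inspected in standard phylogenetics tools.
#'
#' @param matrix Samples x markers 0/1/NA matrix.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_nexus_matrix <- function(matrix, path) {
  ids <- rownames(matrix)
  chr <- apply(matrix, 1, function(r)
    paste(ifelse(is.na(r), "?", r), collapse = ""))
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(matrix),
                     ncol(matrix)),
             "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
             "  MATRIX",
             sprintf("    %s %s", ids, chr),
             "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}
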