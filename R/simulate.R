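#' Simulation configuration
#'
#' The stated world of the synthetic cohorts: four non-progressors and four
#' progressors; non-progressors contribute 3 endoscopic biopsies at each of
#' two time points (mean interval 79 months), progressors 3 endoscopic
#' biopsies at time point 1 and 8 surgical biopsies at time point 2 (mean
#' interval 30 months); every biopsy is split into 4 baguette sections with
#' 2 adjacent crypts each (8 crypts) plus the remaining epithelium, 9
#' samples per biopsy. Crypt lineages follow a constant-size coalescent;
#' breakpoint events accrue along branches at
#' `lambda x 2 alleles x loci` per year, modulated by branch-local rate
#' multipliers and by an exponential gradient in the distance from the
#' gastro-esophageal junction; the default crypt-level rates are 0.005
#' (non-progressors) and 0.013 (progressors) events/allele copy/locus/year.
#'
#' @param n_patients_per_arm Patients per arm.
#' @param grid `genome_grid` (default [toy_genome_grid()]).
#' @param crypts_per_biopsy Crypts per biopsy (4 sections x 2 slots).
#' @param biopsies_np,biopsies_p Biopsies at time points 1 and 2 per arm.
#' @param age_at_t1 Age at first sampling (years).
#' @param months_np,months_p Months between time points per arm.
#' @param lambda_np,lambda_p True SCA rates per arm
#'   (events/allele copy/locus/year).
#' @param rho Gain fraction of events.
#' @param onset_age Age of the founder (unaltered ancestor) in years.
#' @param Ne_tau Coalescent scale of the biopsy-ancestor genealogy, years.
#' @param Ne_within Coalescent scale of the crypts within one biopsy, years;
#'   crypts of a biopsy form a local clade (clonal patches at the
#'   millimetre scale), whose ancestor lineages then coalesce across the
#'   segment with scale `Ne_tau`.
#' @param founder_events Clonal events on the stem above the crypt MRCA.
#' @param n_rlc_shifts,rlc_multiplier Branch-local rate shifts.
#' @param n_gd Genome-doubling events placed on random internal branches.
#' @param gej_beta Rate gradient: branch rates are multiplied by
#'   `exp(-gej_beta x distance-from-GEJ)` of the destination biopsy.
#' @param gej_max_cm Biopsy positions are drawn uniformly on
#'   `[0, gej_max_cm]` cm from the GEJ.
#' @param event_mode `"marker"` (constant-rate single-locus breakpoint
#'   events) or `"ctmc"` (exact per-allele-copy birth-death chain per
#'   locus).
#' @param unique_events In marker mode, force unique-origin events: no two
#'   events share a locus, a breakpoint boundary, or a boundary position on
#'   the other allele (errors if the toy genome is exhausted). Guarantees
#'   exact pipeline closure (markers = truth, no homoplasy); the relaxed
#'   default allows recurrent breakpoints, as real genomes do.
#' @param K Copy-state cap.
#' @param f_consensus Fraction of a biopsy's crypts that must carry an event
#'   for the epithelium profile to contain it, in `[0.5, 1]`.
#' @param p_fn Per-event dropout probability in crypt profiles.
#' @param spurious_rate Expected spurious single-locus events per crypt.
#' @param scramble_phase Randomly swap allele labels per chromosome per
#'   sample before output (undone by [phase_alleles()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients_per_arm = 4,
                       grid = toy_genome_grid(),
                       crypts_per_biopsy = 8L,
                       biopsies_np = c(3L, 3L), biopsies_p = c(3L, 8L),
                       age_at_t1 = 60, months_np = 79, months_p = 30,
                       lambda_np = 0.005, lambda_p = 0.013, rho = 0.5,
                       onset_age = 40, Ne_tau = 5, Ne_within = 1,
                       founder_events = 4L,
                       n_rlc_shifts = 0L, rlc_multiplier = 10,
                       n_gd = 0L, gej_beta = 0.2, gej_max_cm = 10,
                       event_mode = c("marker", "ctmc"),
                       unique_events = FALSE, K = 4L,
                       f_consensus = 0.5, p_fn = 0.1, spurious_rate = 0.5,
                       scramble_phase = TRUE) {
  event_mode <- match.arg(event_mode)
  if (f_consensus < 0.5 || f_consensus > 1)
    stop("f_consensus must lie in [0.5, 1]")
  if (p_fn < 0 || p_fn > 1 || spurious_rate < 0)
    stop("invalid noise configuration")
  if (onset_age >= age_at_t1) stop("onset must predate first sampling")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

n_loci_of <- function(grid) nrow(grid_segments(grid))

# Two-level genealogy: crypts of each biopsy coalesce locally (scale
# Ne_within), then the biopsy ancestor lineages coalesce across the segment
# (scale Ne_tau). Returns one clock tree over all crypt tips.
sim_patient_genealogy <- function(tip_ages, biopsy_of, Ne_within, Ne_tau) {
  bios <- unique(biopsy_of)
  subtrees <- list()
  anc_age <- numeric(length(bios))
  names(anc_age) <- bios
  for (b in bios) {
    tips_b <- tip_ages[biopsy_of == b]
    subtrees[[b]] <- if (length(tips_b) == 1L)
      list(tip_label = names(tips_b), parent = 0L, age = unname(tips_b),
           root = 1L)
    else sim_coalescent_tree(tips_b, Ne_within)
    anc_age[b] <- subtrees[[b]]$age[subtrees[[b]]$root]
  }
  if (length(bios) == 1L) {
    st <- subtrees[[bios]]
    return(list(tip_label = st$tip_label,
                parent = st$parent, age = st$age, root = st$root))
  }
  top <- sim_coalescent_tree(anc_age, Ne_tau)
  # merge: number all crypt tips first, then all internal nodes
  n <- length(tip_ages)
  parent <- integer(2L * n - 1L)
  age <- numeric(2L * n - 1L)
  tip_label <- names(tip_ages)
  age[seq_len(n)] <- tip_ages
  next_int <- n
  map_global <- function(st, local_tip_ids) {
    # returns the global id of the subtree root; fills parent/age
    nl <- length(st$tip_label)
    gid <- integer(length(st$parent))
    gid[seq_len(nl)] <- local_tip_ids
    for (v in seq_len(length(st$parent) - nl) + nl) {
      next_int <<- next_int + 1L
      gid[v] <- next_int
      age[next_int] <<- st$age[v]
    }
    for (v in seq_along(st$parent)) {
      if (st$parent[v] > 0) parent[gid[v]] <<- gid[st$parent[v]]
    }
    gid[st$root]
  }
  roots_b <- vapply(bios, function(b)
    map_global(subtrees[[b]], which(biopsy_of == b)), 0L)
  names(roots_b) <- bios
  top_gid <- integer(length(top$parent))
  n_bio <- length(bios)
  top_gid[seq_len(n_bio)] <- roots_b[top$tip_label]
  for (v in (n_bio + 1L):length(top$parent)) {
    next_int <- next_int + 1L
    top_gid[v] <- next_int
    age[next_int] <- top$age[v]
  }
  for (v in seq_along(top$parent)) {
    if (top$parent[v] > 0) parent[top_gid[v]] <- top_gid[top$parent[v]]
  }
  list(tip_label = tip_label, parent = parent, age = age,
       root = top_gid[top$root])
}

# Pick an unused, interior locus/allele for a unique-origin event. A locus
# already hit on either allele is excluded (two alleles breaking at one
# boundary would make allele phasing ambiguous), as are loci adjacent to a
# used locus (events must not share breakpoint boundaries).
pick_unique_site <- function(used, grid_seg, chrom = NULL, strict = TRUE) {
  if (strict) {
    pos_used <- used[, 1] | used[, 2]
    blocked <- cbind(pos_used, pos_used)
    ok <- !blocked & !grid_seg$terminal & !used_neighbour(blocked, grid_seg)
  } else {
    ok <- cbind(!grid_seg$terminal, !grid_seg$terminal)
  }
  if (!is.null(chrom)) ok <- ok & grid_seg$chrom == chrom
  cand <- which(ok, arr.ind = TRUE)
  if (!nrow(cand))
    stop("toy genome exhausted: too many unique events; ",
         "use unique_events = FALSE or a larger genome")
  i <- cand[sample.int(nrow(cand), 1), , drop = TRUE]
  c(locus = unname(i[1]), allele = unname(i[2]))
}

used_neighbour <- function(used, grid_seg) {
  n <- nrow(used)
  shift_up <- rbind(used[-1, , drop = FALSE], FALSE)
  shift_dn <- rbind(FALSE, used[-n, , drop = FALSE])
  same_chrom_up <- c(grid_seg$chrom[-1] == grid_seg$chrom[-n], FALSE)
  same_chrom_dn <- c(FALSE, grid_seg$chrom[-n] == grid_seg$chrom[-1])
  (shift_up & same_chrom_up) | (shift_dn & same_chrom_dn)
}

#' Simulate one patient
#'
#' Draws the crypt genealogy, places founder, branch and genome-doubling
#' events, assembles crypt and biopsy-epithelium profiles, applies crypt
#' measurement noise, and returns everything alongside the ground truth.
#'
#' @param config A [sim_config()].
#' @param patient_id Patient identifier.
#' @param progressor Logical.
#' @param seed Integer seed.
#' @return List: `profiles` (named list of `segment_profile`, noisy, allele
#'   labels scrambled if configured), `patients`/`samples` metadata
#'   data.frames, and `truth` (tree, events, per-sample event ids, pre-noise
#'   profiles, GD samples, parameters).
#' @export
simulate_patient <- function(config, patient_id = "P1", progressor = FALSE,
                             seed = 1L) {
  set.seed(seed)
  cfg <- config
  grid_seg <- grid_segments(cfg$grid)
  n_loci <- nrow(grid_seg)
  chrom_of <- grid_seg$chrom
  first_of_chrom <- !duplicated(chrom_of)
  last_of_chrom <- rev(!duplicated(rev(chrom_of)))
  grid_seg$terminal <- first_of_chrom | last_of_chrom
  lambda <- if (progressor) cfg$lambda_p else cfg$lambda_np
  months <- if (progressor) cfg$months_p else cfg$months_np
  design <- if (progressor) cfg$biopsies_p else cfg$biopsies_np
  age_t2 <- cfg$age_at_t1 + months / 12

  # --- biopsies and crypt tips ---
  n_bio <- sum(design)
  bio <- data.frame(
    biopsy_id = sprintf("B%d", seq_len(n_bio)),
    time_point = rep(c(1L, 2L), design),
    gej_cm = round(stats::runif(n_bio, 0, cfg$gej_max_cm), 1))
  bio$age <- ifelse(bio$time_point == 1L, cfg$age_at_t1, age_t2)
  sec <- rep(1:4, each = 2)[seq_len(cfg$crypts_per_biopsy)]
  slot <- rep(c("a", "b"), 4)[seq_len(cfg$crypts_per_biopsy)]
  crypts <- do.call(rbind, lapply(seq_len(n_bio), function(b)
    data.frame(sample_id = sprintf("%s.%s.c%d%s", patient_id,
                                   bio$biopsy_id[b], sec, slot),
               biopsy_id = bio$biopsy_id[b], section = sec, slot = slot,
               time_point = bio$time_point[b], gej_cm = bio$gej_cm[b],
               age = bio$age[b])))
  tip_ages <- stats::setNames(crypts$age, crypts$sample_id)

  # --- genealogy (rejection: crypt MRCA must postdate the founder) ---
  ct <- NULL
  for (i in 1:1000) {
    ct <- sim_patient_genealogy(tip_ages, crypts$biopsy_id,
                                cfg$Ne_within, cfg$Ne_tau)
    if (ct$age[ct$root] > cfg$onset_age) break
  }
  if (ct$age[ct$root] <= cfg$onset_age)
    stop("coalescent deeper than the onset age; decrease Ne_tau")
  nv <- length(ct$parent)
  n_tips <- nrow(crypts)

  # --- per-branch rate factors ---
  gejf_tip <- exp(-cfg$gej_beta * crypts$gej_cm)
  desc_tips <- vector("list", nv)
  for (v in clock_tree_postorder(ct)) {
    if (v <= n_tips) desc_tips[[v]] <- v
    p <- ct$parent[v]
    if (p > 0) desc_tips[[p]] <- c(desc_tips[[p]], desc_tips[[v]])
  }
  gejf <- vapply(desc_tips, function(d) mean(gejf_tip[d]), 0)
  internals <- setdiff(seq_len(nv), c(seq_len(n_tips), ct$root))
  rlc_nodes <- integer(0)
  mult <- rep(1, nv)
  if (cfg$n_rlc_shifts > 0) {
    rlc_nodes <- sample(internals, min(cfg$n_rlc_shifts, length(internals)))
    mult[rlc_nodes] <- cfg$rlc_multiplier
  }
  eff <- rlc_effective(ct, as.integer(mult != 1), mult)
  gd_nodes <- integer(0)
  if (cfg$n_gd > 0) {
    pool <- setdiff(internals, rlc_nodes)
    if (!length(pool)) pool <- internals
    gd_nodes <- sample(pool, min(cfg$n_gd, length(pool)))
  }

  if (cfg$event_mode == "ctmc") {
    return(simulate_patient_ctmc(cfg, patient_id, progressor, ct, crypts,
                                 bio, eff, gejf, gd_nodes, lambda, months,
                                 grid_seg, seed))
  }

  # --- events ---
  used <- matrix(FALSE, n_loci, 2)
  events <- list()
  add_event <- function(node, time, locus, allele, delta) {
    events[[length(events) + 1L]] <<- data.frame(
      event_id = length(events) + 1L, node = node, time = time,
      locus = locus, allele = allele, delta = delta)
  }
  draw_events <- function(node, t0, t1, rate_mult) {
    dt <- t1 - t0
    n_ev <- stats::rpois(1, lambda * 2 * n_loci * rate_mult * dt)
    if (n_ev == 0) return()
    times <- sort(stats::runif(n_ev, t0, t1))
    for (tm in times) {
      site <- pick_unique_site(used, grid_seg, strict = cfg$unique_events)
      used[site["locus"], site["allele"]] <<- TRUE
      delta <- if (stats::runif(1) < cfg$rho) 1L else -1L
      add_event(node, tm, site["locus"], site["allele"], delta)
    }
  }
  # founder (clonal) events on the stem, spread one per chromosome so every
  # chromosome carries a clonal anchor for allele phasing
  stem_times <- sort(stats::runif(cfg$founder_events, cfg$onset_age,
                                  ct$age[ct$root]))
  chrom_cycle <- rep_len(unique(grid_seg$chrom), cfg$founder_events)
  for (i in seq_along(stem_times)) {
    site <- pick_unique_site(used, grid_seg, chrom = chrom_cycle[i])
    used[site["locus"], site["allele"]] <- TRUE
    delta <- if (stats::runif(1) < cfg$rho) 1L else -1L
    add_event(ct$root, stem_times[i], site["locus"], site["allele"], delta)
  }
  for (v in seq_len(nv)) {
    p <- ct$parent[v]
    if (p == 0) next
    draw_events(v, ct$age[p], ct$age[v], eff[v] * gejf[v])
  }
  events <- if (length(events)) do.call(rbind, events)
            else data.frame(event_id = integer(0), node = integer(0),
                            time = numeric(0), locus = integer(0),
                            allele = integer(0), delta = integer(0))

  # --- replay events along root-to-tip paths ---
  path_to <- function(v) {
    out <- integer(0)
    while (v != 0) { out <- c(v, out); v <- ct$parent[v] }
    out
  }
  gd_time <- stats::setNames(
    (ct$age[gd_nodes] + ct$age[ct$parent[gd_nodes]]) / 2,
    gd_nodes)
  replay <- function(nodes) {
    st <- matrix(1L, n_loci, 2)
    for (v in nodes) {
      ev <- events[events$node == v, ]
      acts <- rbind(
        if (nrow(ev)) data.frame(time = ev$time, what = "ev",
                                 i = seq_len(nrow(ev)) + 0,
                                 locus = ev$locus, allele = ev$allele,
                                 delta = ev$delta),
        if (v %in% gd_nodes) data.frame(time = gd_time[[as.character(v)]],
                                        what = "gd", i = 0, locus = 0,
                                        allele = 0, delta = 0))
      if (is.null(acts) || !nrow(acts)) next
      acts <- acts[order(acts$time), ]
      for (r in seq_len(nrow(acts))) {
        if (acts$what[r] == "gd") st <- st * 2L
        else {
          l <- acts$locus[r]; a <- acts$allele[r]
          st[l, a] <- min(max(0L, st[l, a] + acts$delta[r]), cfg$K)
        }
      }
    }
    st
  }
  crypt_states <- lapply(seq_len(n_tips), function(i) replay(path_to(i)))
  crypt_events <- lapply(seq_len(n_tips), function(i) {
    nodes <- path_to(i)
    events$event_id[events$node %in% nodes]
  })
  crypt_gd <- vapply(seq_len(n_tips), function(i)
    any(path_to(i) %in% gd_nodes), TRUE)

  # --- biopsy epithelium: consensus over constituent crypts ---
  thr <- ceiling(cfg$f_consensus * cfg$crypts_per_biopsy)
  bio_states <- list()
  bio_events <- list()
  bio_gd <- logical(n_bio)
  for (b in seq_len(n_bio)) {
    members <- which(crypts$biopsy_id == bio$biopsy_id[b])
    carried <- table(unlist(crypt_events[members]))
    keep_ids <- as.integer(names(carried)[carried >= thr])
    qual_gd <- gd_nodes[vapply(gd_nodes, function(g)
      sum(vapply(members, function(m) g %in% path_to(m), TRUE)) >= thr,
      TRUE)]
    bio_gd[b] <- length(qual_gd) > 0
    gd_when <- if (bio_gd[b]) min(gd_time[as.character(qual_gd)]) else Inf
    ev <- events[events$event_id %in% keep_ids, ]
    acts <- ev[order(ev$time), ]
    st <- matrix(1L, n_loci, 2)
    done_gd <- FALSE
    for (r in seq_len(nrow(acts))) {
      if (!done_gd && acts$time[r] > gd_when) { st <- st * 2L; done_gd <- TRUE }
      l <- acts$locus[r]; a <- acts$allele[r]
      st[l, a] <- min(max(0L, st[l, a] + acts$delta[r]), cfg$K)
    }
    if (!done_gd && is.finite(gd_when)) st <- st * 2L
    bio_states[[b]] <- st
    bio_events[[b]] <- acts$event_id
  }

  # --- profiles ---
  state_to_profile <- function(st, sid, phased = TRUE) {
    segment_profile(data.frame(chrom = grid_seg$chrom,
                               start = grid_seg$start, end = grid_seg$end,
                               cn1 = st[, 1], cn2 = st[, 2]),
                    sid, phased = phased)
  }
  crypt_ids <- crypts$sample_id
  epi_ids <- sprintf("%s.%s.epi", patient_id, bio$biopsy_id)
  truth_profiles <- c(
    stats::setNames(lapply(seq_len(n_tips), function(i)
      state_to_profile(crypt_states[[i]], crypt_ids[i])), crypt_ids),
    stats::setNames(lapply(seq_len(n_bio), function(b)
      state_to_profile(bio_states[[b]], epi_ids[b])), epi_ids))

  # --- crypt noise, then optional label scrambling ---
  founder_state <- {
    st <- matrix(1L, n_loci, 2)
    fe <- events[events$node == ct$root, ]
    for (r in seq_len(nrow(fe)))
      st[fe$locus[r], fe$allele[r]] <-
        min(max(0L, st[fe$locus[r], fe$allele[r]] + fe$delta[r]), cfg$K)
    st
  }
  noisy <- truth_profiles
  if (cfg$p_fn > 0 || cfg$spurious_rate > 0) {
    noisy[crypt_ids] <- degrade(truth_profiles[crypt_ids],
                                p_fn = cfg$p_fn,
                                spurious_rate = cfg$spurious_rate,
                                founder = founder_state,
                                seed = seed + 1L)
  }
  scramble <- NULL
  if (cfg$scramble_phase) {
    chroms <- unique(grid_seg$chrom)
    scramble <- matrix(stats::runif(length(noisy) * length(chroms)) < 0.5,
                       length(noisy), length(chroms),
                       dimnames = list(names(noisy), chroms))
    for (s in names(noisy)) {
      p <- noisy[[s]]
      for (chx in chroms[scramble[s, ]]) p <- flip_chromosome(p, chx)
      attr(p, "phased") <- FALSE
      noisy[[s]] <- p
    }
  }

  # --- metadata ---
  patients <- data.frame(patient_id = patient_id, progressor = progressor,
                         age_at_t1 = cfg$age_at_t1,
                         months_between_timepoints = months)
  samples <- rbind(
    data.frame(sample_id = crypt_ids, patient_id = patient_id,
               role = "crypt", time_point = crypts$time_point,
               biopsy_id = crypts$biopsy_id,
               baguette_section = crypts$section, crypt_slot = crypts$slot,
               gej_distance_cm = crypts$gej_cm,
               sampling_age_years = crypts$age),
    data.frame(sample_id = epi_ids, patient_id = patient_id,
               role = "biopsy_epithelium", time_point = bio$time_point,
               biopsy_id = bio$biopsy_id, baguette_section = NA,
               crypt_slot = NA, gej_distance_cm = bio$gej_cm,
               sampling_age_years = bio$age))
  truth <- list(
    tree = ct, lambda = lambda, rho = cfg$rho, Ne_tau = cfg$Ne_tau,
    onset_age = cfg$onset_age, events = events,
    sample_events = c(stats::setNames(crypt_events, crypt_ids),
                      stats::setNames(bio_events, epi_ids)),
    gd_nodes = gd_nodes,
    gd_samples = c(stats::setNames(crypt_gd, crypt_ids),
                   stats::setNames(bio_gd, epi_ids)),
    rlc_nodes = rlc_nodes, branch_multiplier = mult,
    profiles = truth_profiles, founder_state = founder_state,
    scramble = scramble)
  list(profiles = noisy, patients = patients, samples = samples,
       truth = truth)
}

# Exact-chain variant of simulate_patient: every locus x allele evolves as
# an independent per-allele-copy birth-death chain along the genealogy;
# biopsy epithelium takes the per-cell state shared by >= f of its crypts
# (founder state otherwise). No event bookkeeping, so pipeline-closure
# identities hold only in "marker" mode.
simulate_patient_ctmc <- function(cfg, patient_id, progressor, ct, crypts,
                                  bio, eff, gejf, gd_nodes, lambda, months,
                                  grid_seg, seed) {
  n_loci <- nrow(grid_seg)
  n_tips <- nrow(crypts)
  nv <- length(ct$parent)
  n_bio <- nrow(bio)
  states <- vector("list", nv)
  stem <- ct$age[ct$root] - cfg$onset_age
  evolve_mat <- function(parent_st, s) {
    out <- parent_st
    for (i in seq_along(out))
      out[i] <- evolve_chain_state(out[i], s, cfg$rho, cfg$K)
    out
  }
  states[[ct$root]] <- evolve_mat(matrix(1L, n_loci, 2), lambda * stem)
  for (v in rev(clock_tree_postorder(ct))) {
    p <- ct$parent[v]
    if (p == 0) next
    s <- lambda * eff[v] * gejf[v] * (ct$age[v] - ct$age[p])
    st <- evolve_mat(states[[p]], s)
    if (v %in% gd_nodes) st <- pmin(st * 2L, cfg$K * 2L)
    states[[v]] <- st
  }
  path_to <- function(v) {
    out <- integer(0)
    while (v != 0) { out <- c(v, out); v <- ct$parent[v] }
    out
  }
  crypt_gd <- vapply(seq_len(n_tips), function(i)
    any(path_to(i) %in% gd_nodes), TRUE)
  thr <- ceiling(cfg$f_consensus * cfg$crypts_per_biopsy)
  bio_states <- lapply(seq_len(n_bio), function(b) {
    members <- which(crypts$biopsy_id == bio$biopsy_id[b])
    st <- matrix(1L, n_loci, 2)
    for (a in 1:2) for (l in seq_len(n_loci)) {
      vals <- vapply(members, function(m) states[[m]][l, a], 0L)
      tab <- table(vals)
      top <- as.integer(names(tab)[which.max(tab)])
      if (max(tab) >= thr) st[l, a] <- top
    }
    st
  })
  bio_gd <- vapply(seq_len(n_bio), function(b)
    sum(crypt_gd[crypts$biopsy_id == bio$biopsy_id[b]]) >= thr, TRUE)
  state_to_profile <- function(st, sid)
    segment_profile(data.frame(chrom = grid_seg$chrom,
                               start = grid_seg$start, end = grid_seg$end,
                               cn1 = st[, 1], cn2 = st[, 2]),
                    sid, phased = TRUE)
  crypt_ids <- crypts$sample_id
  epi_ids <- sprintf("%s.%s.epi", patient_id, bio$biopsy_id)
  truth_profiles <- c(
    stats::setNames(lapply(seq_len(n_tips), function(i)
      state_to_profile(states[[i]], crypt_ids[i])), crypt_ids),
    stats::setNames(lapply(seq_len(n_bio), function(b)
      state_to_profile(bio_states[[b]], epi_ids[b])), epi_ids))
  patients <- data.frame(patient_id = patient_id, progressor = progressor,
                         age_at_t1 = cfg$age_at_t1,
                         months_between_timepoints = months)
  samples <- rbind(
    data.frame(sample_id = crypt_ids, patient_id = patient_id,
               role = "crypt", time_point = crypts$time_point,
               biopsy_id = crypts$biopsy_id,
               baguette_section = crypts$section, crypt_slot = crypts$slot,
               gej_distance_cm = crypts$gej_cm,
               sampling_age_years = crypts$age),
    data.frame(sample_id = epi_ids, patient_id = patient_id,
               role = "biopsy_epithelium", time_point = bio$time_point,
               biopsy_id = bio$biopsy_id, baguette_section = NA,
               crypt_slot = NA, gej_distance_cm = bio$gej_cm,
               sampling_age_years = bio$age))
  truth <- list(tree = ct, lambda = lambda, rho = cfg$rho,
                Ne_tau = cfg$Ne_tau, onset_age = cfg$onset_age,
                events = NULL, gd_nodes = gd_nodes,
                gd_samples = c(stats::setNames(crypt_gd, crypt_ids),
                               stats::setNames(bio_gd, epi_ids)),
                profiles = truth_profiles)
  list(profiles = truth_profiles, patients = patients, samples = samples,
       truth = truth)
}

#' Apply crypt measurement noise to profiles
#'
#' Each departure of a crypt profile from the founder (clonal) state at a
#' (locus, allele) is treated as one detected event and is dropped — the
#' cell reverts to the founder state — independently with probability
#' `p_fn`; spurious single-locus events (a random +/-1 on a random cell)
#' are added at rate `spurious_rate` per profile. With `p_fn = 1` every
#' crypt reverts to the founder state.
#'
#' @param profiles Named list of `segment_profile` (crypts).
#' @param p_fn Dropout probability per event.
#' @param spurious_rate Expected spurious events per profile.
#' @param founder Loci x 2 matrix of founder allele states (default all 1).
#' @param seed Integer seed.
#' @return Named list of degraded profiles.
#' @export
degrade <- function(profiles, p_fn = 0.1, spurious_rate = 0.5,
                    founder = NULL, seed = 1L) {
  set.seed(seed)
  lapply(profiles, function(p) {
    st <- cbind(p$cn1, p$cn2)
    fs <- if (is.null(founder)) matrix(1L, nrow(st), 2) else founder
    dev <- which(st != fs, arr.ind = TRUE)
    if (nrow(dev)) {
      drop <- stats::runif(nrow(dev)) < p_fn
      for (r in which(drop)) st[dev[r, 1], dev[r, 2]] <- fs[dev[r, 1], dev[r, 2]]
    }
    n_sp <- stats::rpois(1, spurious_rate)
    for (k in seq_len(n_sp)) {
      l <- sample.int(nrow(st), 1)
      a <- sample.int(2, 1)
      d <- if (st[l, a] == 0L) 1L else sample(c(-1L, 1L), 1)
      st[l, a] <- max(0L, st[l, a] + d)
    }
    out <- p
    out$cn1 <- st[, 1]
    out$cn2 <- st[, 2]
    out
  })
}

#' Simulate a full cohort and write it in ingest formats
#'
#' Runs [simulate_patient()] for every patient of both arms under the
#' default sampling design (yielding 612 samples for the default
#' configuration) and writes `segments.tsv`, `samples.csv` and `truth.json`
#' into `out_dir`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; patient seeds are derived from it.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return Invisibly, a named list of per-patient [simulate_patient()]
#'   results.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L,
                            out_dir = NULL) {
  arms <- c(rep(FALSE, config$n_patients_per_arm),
            rep(TRUE, config$n_patients_per_arm))
  ids <- c(sprintf("NP%d", seq_len(config$n_patients_per_arm)),
           sprintf("PR%d", seq_len(config$n_patients_per_arm)))
  res <- lapply(seq_along(ids), function(i)
    simulate_patient(config, ids[i], arms[i], seed = seed * 1000L + i))
  names(res) <- ids
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    all_prof <- do.call(c, lapply(res, `[[`, "profiles"))
    write_segment_table(all_prof, file.path(out_dir, "segments.tsv"))
    metas <- list(
      patients = do.call(rbind, lapply(res, `[[`, "patients")),
      samples = do.call(rbind, lapply(res, `[[`, "samples")))
    rownames(metas$patients) <- rownames(metas$samples) <- NULL
    write_sample_sheet(metas, file.path(out_dir, "samples.csv"))
    truth <- lapply(res, function(r) list(
      lambda = r$truth$lambda, rho = r$truth$rho,
      Ne_tau = r$truth$Ne_tau, onset_age = r$truth$onset_age,
      n_events = if (is.null(r$truth$events)) NA_integer_
                 else nrow(r$truth$events),
      gd_samples = names(which(r$truth$gd_samples)),
      tree = ape::write.tree(clock_tree_as_phylo(r$truth$tree))))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}
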