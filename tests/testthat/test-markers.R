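test_that("breakpoints are extracted at interior and edge boundaries", {
  grid <- tiny_grid()   # 2 chromosomes x 5 loci of 2 Mb
  # all-normal profile -> no markers
  p0 <- profile_from_states(grid, rep(1, 10), rep(1, 10))
  expect_equal(nrow(extract_breakpoints(p0)), 0)

  # single interior loss on allele 1, chromosome 1 loci 2-3
  p1 <- profile_from_states(grid, c(1, 0, 0, 1, 1, rep(1, 5)), rep(1, 10))
  bp <- extract_breakpoints(p1)
  expect_equal(bp$pos, c(2e6, 6e6))
  expect_equal(bp$allele, c(1L, 1L))
  expect_equal(bp$cn_left, c(1L, 0L))
  expect_equal(bp$cn_right, c(0L, 1L))

  # whole-chromosome cnLOH -> edge markers on both alleles
  p2 <- profile_from_states(grid, c(rep(2, 5), rep(1, 5)),
                            c(rep(0, 5), rep(1, 5)))
  bp2 <- extract_breakpoints(p2)
  expect_setequal(bp2$marker_id,
                  c("1:0:a1", "1:10000000:a1", "1:0:a2", "1:10000000:a2"))
  expect_error(extract_breakpoints(profile_from_states(
    grid, rep(1, 10), rep(1, 10), phased = FALSE)), "phased")
})

test_that("character matrix matches simulator ground truth", {
  cfg <- sim_config(n_patients_per_arm = 1, biopsies_np = c(2L, 1L),
                    p_fn = 0, spurious_rate = 0,
                    n_gd = 1, unique_events = TRUE,
                    grid = toy_genome_grid(locus_bp = 1e6))
  sim <- simulate_patient(cfg, "X", FALSE, seed = 21)
  ph <- phase_alleles(sim$profiles)
  got <- build_character_matrix(ph)
  want <- build_character_matrix(sim$truth$profiles)
  fp <- function(m) unname(sort(apply(m[order(rownames(m)), ] == 1, 2,
                                      paste, collapse = "")))
  expect_identical(fp(got$matrix), fp(want$matrix))
  # column sums = number of carriers per event boundary
  expect_identical(sort(unname(colSums(got$matrix))),
                   sort(unname(colSums(want$matrix))))
})

test_that("phasing distinguishes shared from independent losses", {
  grid <- tiny_grid()
  # two samples losing the SAME haplotype at one locus: simulator truth has
  # both on allele 1; the ingest labels of s2 are scrambled
  s1 <- profile_from_states(grid, c(1, 0, 1, 1, 1, rep(1, 5)), rep(1, 10),
                            "s1", phased = FALSE)
  s2_scrambled <- profile_from_states(grid, rep(1, 10),
                                      c(1, 0, 1, 1, 1, rep(1, 5)),
                                      "s2", phased = FALSE)
  ph <- phase_alleles(list(s1, s2_scrambled))
  m1 <- extract_breakpoints(ph[[1]])$marker_id
  m2 <- extract_breakpoints(ph[[2]])$marker_id
  expect_identical(m1, m2)   # recognised as the same allele-specific event

  # independent losses of opposite haplotypes stay on different alleles.
  # Truth: both samples share an anchor loss (locus 2, allele 1); each has a
  # private loss on a separate locus, s3 on allele 1 and s4 on allele 2.
  # s4's incoming labels are scrambled; the anchor forces the flip back.
  g2 <- toy_genome_grid(n_chrom = 1, chrom_len = 20e6, locus_bp = 2e6)
  st <- function(loci) replace(rep(1, 10), loci, 0)
  s3 <- profile_from_states(g2, st(c(2, 4)), rep(1, 10), "s3",
                            phased = FALSE)
  s4 <- profile_from_states(g2, st(7), st(2), "s4",
                            phased = FALSE)   # anchor on cn2 = scrambled
  ph2 <- phase_alleles(list(s3, s4))
  m3 <- extract_breakpoints(ph2[[1]])
  m4 <- extract_breakpoints(ph2[[2]])
  expect_equal(m3$allele[m3$pos %in% c(2e6, 4e6)],
               m4$allele[m4$pos %in% c(2e6, 4e6)])   # anchor shared
  priv3 <- unique(m3$allele[m3$pos %in% c(6e6, 8e6)])
  priv4 <- unique(m4$allele[m4$pos %in% c(12e6, 14e6)])
  expect_length(priv3, 1)
  expect_length(priv4, 1)
  expect_true(priv3 != priv4)      # private losses on opposite alleles
  # global label flip leaves shared/private counts unchanged
  flip_all <- lapply(ph2, function(p) {
    q <- p
    for (ch in unique(p$chrom)) q <- cryptclock:::flip_chromosome(q, ch)
    attr(q, "phased") <- TRUE
    q
  })
  cm_a <- build_character_matrix(ph2)$matrix
  cm_b <- build_character_matrix(flip_all)$matrix
  expect_identical(sort(unname(colSums(cm_a))), sort(unname(colSums(cm_b))))
})

test_that("clonal markers are the exact NA-conservative intersection", {
  m <- matrix(c(1, 1, 1,
                1, 0, 1,
                1, NA, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("m1", "m2", "m3")))
  expect_identical(clonal_markers(m), c("m1", "m3"))
  expect_length(clonal_markers(m[, 2, drop = FALSE]), 0)
})

test_that("crypt/biopsy divergence counts private and missing markers", {
  samples <- data.frame(
    sample_id = c("c1", "c2", "epi"), patient_id = "P",
    role = c("crypt", "crypt", "biopsy_epithelium"),
    time_point = 1L, biopsy_id = "B1",
    baguette_section = c(1L, 2L, NA), crypt_slot = c("a", "a", NA),
    gej_distance_cm = 1, sampling_age_years = 60)
  m <- matrix(0L, 3, 10, dimnames = list(c("c1", "c2", "epi"),
                                         paste0("m", 1:10)))
  m["epi", 1:8] <- 1L
  m["c1", 1:10] <- 1L          # 2 private, 0 missing, 10 informative
  # c2 identical to the biopsy
  m["c2", 1:8] <- 1L
  d <- crypt_biopsy_divergence(m, samples)
  expect_equal(d$n_private_to_crypt, c(2, 0))
  expect_equal(d$n_missing_from_crypt, c(0, 0))
  expect_equal(d$pct_divergent, c(20, 0))
  # biopsy-only markers -> 100% divergent crypt
  m["c2", ] <- 0L
  d2 <- crypt_biopsy_divergence(m, samples)
  expect_equal(d2$pct_divergent[2], 100)
  expect_equal(d2$n_missing_from_crypt[2], 8)
  # missing parent biopsy is an error
  expect_error(crypt_biopsy_divergence(m[1:2, ], samples[1:2, ]), "parent")
})

test_that("window distance is a symmetric percentage with exact toy value", {
  grid <- tiny_grid()   # two 10 Mb chromosomes -> 20 windows of 1 Mb
  a <- profile_from_states(grid, rep(1, 10), rep(1, 10), "a")
  b <- profile_from_states(grid, c(2, rep(1, 9)), rep(1, 10), "b")
  expect_equal(window_distance(a, a), 0)
  # one 2 Mb locus differs -> 2 of 20 windows
  expect_equal(window_distance(a, b), 10)
  set.seed(1)
  for (i in 1:5) {
    x <- profile_from_states(grid, sample(0:2, 10, TRUE), rep(1, 10), "x")
    y <- profile_from_states(grid, sample(0:2, 10, TRUE), rep(1, 10), "y")
    expect_equal(window_distance(x, y), window_distance(y, x))
    expect_gte(window_distance(x, y), 0)
    expect_lte(window_distance(x, y), 100)
  }
})

test_that("NEXUS export is well-formed", {
  m <- matrix(c(1L, 0L, NA, 1L), 2, 2,
              dimnames = list(c("s1", "s2"), c("m1", "m2")))
  path <- withr::local_tempfile(fileext = ".nex")
  write_nexus_matrix(m, path)
  txt <- readLines(path)
  expect_equal(txt[1], "#NEXUS")
  expect_true(any(grepl("NTAX=2 NCHAR=2", txt)))
  expect_true(any(grepl("s1 1\\?", txt)))
})
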