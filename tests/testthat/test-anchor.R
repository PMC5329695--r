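test_that("self-alignment yields the identity coordinate map", {
  tpl <- ref_template()
  maps <- build_coordinate_maps(tpl)
  expect_true(maps$anchored)
  expect_identical(maps$map[[1]], seq_len(1542))
})

test_that("50 nt flanks shift the map by a constant offset", {
  set.seed(5)
  flank <- function() paste(sample(c("A", "C", "G", "T"), 50, TRUE),
                            collapse = "")
  tpl <- ref_template()
  tpl$sequence <- paste0(flank(), tpl$sequence, flank())
  maps <- build_coordinate_maps(tpl)
  expect_identical(maps$map[[1]], seq_len(1542) + 50L)
})

test_that("an internal deletion produces gap entries but preserves key sites", {
  # remove 3 nt inside the length-variable h6 window (positions 70-72)
  ref <- ecoli_like_reference()
  tpl <- ref_template("del3")
  tpl$sequence <- paste0(substr(ref, 1, 69), substr(ref, 73, 1542))
  maps <- build_coordinate_maps(tpl)
  m <- maps$map[[1]]
  expect_equal(sum(is.na(m)), 3)
  expect_true(all(is.na(m[70:72])))
  expect_equal(m[19], 19L)
  expect_equal(m[916], 913L)
  expect_equal(m[1527], 1524L)
  # non-gap template positions are strictly increasing
  expect_true(all(diff(m[!is.na(m)]) > 0))
})

test_that("alignment score matches a brute-force semi-global DP on small instances", {
  set.seed(17)
  ref250 <- substr(ecoli_like_reference(), 1, 250)
  for (k in 1:5) {
    yc <- strsplit(ref250, "")[[1]]
    subs <- sample(250, 12)
    for (s in subs) yc[s] <- sample(setdiff(c("A", "C", "G", "T"), yc[s]), 1)
    if (k >= 3) yc <- yc[-(90:92)]
    y <- paste(c(sample(c("A", "C", "G", "T"), 15, TRUE), yc,
                 sample(c("A", "C", "G", "T"), 15, TRUE)), collapse = "")
    tpl <- tibble::tibble(id = paste0("t", k), sequence = y,
                          taxon_phylum = "", taxon_class = "",
                          has_flanks = TRUE)
    maps <- build_coordinate_maps(tpl, reference = ref250)
    expect_equal(maps$score, oracle_semiglobal_score(ref250, y))
  }
})

test_that("substitution-only templates recover the identity offset mapping", {
  cfg <- synthetic_config(seed = 21L,
                          n_per_class = c(gamma_like = 5L, beta_like = 5L,
                                          other = 0L),
                          five_prime_variability = 0,
                          flank_length = 50L)
  gen <- generate_templates(cfg)
  maps <- build_coordinate_maps(gen$templates)
  for (i in seq_len(nrow(maps))) {
    expect_identical(maps$map[[i]], seq_len(1542) + 50L)
  }
  # with the hypervariable 1-7 run at its default 0.5 substitution rate the
  # extreme terminus can realign under free end gaps, but the frame from
  # position 8 on (every site the analysis reads) is still recovered exactly
  cfg2 <- synthetic_config(seed = 22L,
                           n_per_class = c(gamma_like = 5L, beta_like = 5L,
                                           other = 0L),
                           flank_length = 50L)
  gen2 <- generate_templates(cfg2)
  maps2 <- build_coordinate_maps(gen2$templates)
  for (i in seq_len(nrow(maps2))) {
    expect_identical(maps2$map[[i]][8:1542], seq.int(8L, 1542L) + 50L)
  }
})

test_that("unanchorable inputs are flagged, and out-of-span queries return NA", {
  short <- tibble::tibble(id = "frag", sequence = strrep("ACGT", 30),
                          taxon_phylum = "", taxon_class = "",
                          has_flanks = FALSE)
  maps <- build_coordinate_maps(short)
  expect_false(maps$anchored)
  expect_true(all(is.na(map_positions(maps, "frag", c(19L, 916L, 1527L)))))
})

test_that("primer footprints land on the intended E. coli coordinates", {
  tpl <- ref_template()
  maps <- build_coordinate_maps(tpl)
  res <- anchor_primers(tpl, amplification_primers(), maps)
  fp <- function(nm) unlist(res[res$primer_name == nm,
                                c("ecoli_start", "ecoli_end", "n_mismatches")])
  expect_equal(fp("Bac1f"), c(ecoli_start = 1, ecoli_end = 18,
                              n_mismatches = 0))
  expect_equal(fp("UN1542r"), c(ecoli_start = 1528, ecoli_end = 1542,
                                n_mismatches = 0))
  expect_equal(fp("Bac8f(A)"), c(ecoli_start = 8, ecoli_end = 27,
                                 n_mismatches = 0))
  expect_equal(fp("UN1541r(U)"), c(ecoli_start = 1525, ecoli_end = 1541,
                                   n_mismatches = 0))
})

test_that("Bac8f(A) on a 19C template mismatches exactly at position 19", {
  tpl <- ref_template("beta_like")
  tpl$sequence <- plant_base(tpl$sequence, 19, "C")
  tpl$sequence <- plant_base(tpl$sequence, 916, "G")
  maps <- build_coordinate_maps(tpl)
  res <- anchor_primers(tpl, primer_by_name("Bac8f(A)"), maps)
  expect_equal(res$n_mismatches, 1)
  expect_equal(res$mismatch_ecoli[[1]], 19L)
  # while the C-version matches cleanly
  res_c <- anchor_primers(tpl, primer_by_name("Bac8f(C)"), maps)
  expect_equal(res_c$n_mismatches, 0)
})

test_that("an exact terminal substring always anchors with zero mismatches", {
  set.seed(31)
  for (k in 1:10) {
    n <- sample(60:300, 1)
    tseq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    L <- sample(12:20, 1)
    fwd <- primer_set("f", substr(tseq, 1, L), "forward")
    rev <- primer_set("r", revcomp(substr(tseq, n - L + 1, n)), "reverse")
    tpl <- tibble::tibble(id = "t", sequence = tseq, taxon_phylum = "",
                          taxon_class = "", has_flanks = FALSE)
    for (p in list(fwd, rev)) {
      res <- anchor_primers(tpl, p, maps = NULL, window = n)
      expect_true(res$anchored)
      expect_equal(res$n_mismatches, 0)
    }
  }
})

test_that("production placement equals the exhaustive all-placements oracle", {
  set.seed(47)
  for (k in 1:12) {
    n <- sample(50:300, 1)
    tseq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    L <- sample(10:18, 1)
    qc <- sample(c("A", "C", "G", "T", "R", "Y", "N"), L, TRUE,
                 prob = c(rep(0.22, 4), 0.05, 0.05, 0.02))
    p <- primer_set("q", paste(qc, collapse = ""), "forward")
    res <- anchor_primers(tibble::tibble(id = "t", sequence = tseq,
                                         taxon_phylum = "", taxon_class = "",
                                         has_flanks = FALSE),
                          p, maps = NULL, window = n)
    orc <- oracle_placements(p$sequence, tseq)
    expect_equal(res$n_mismatches, orc$min)
    # forward tie-break goes to the terminus-proximal optimal placement
    expect_equal(res$tpl_start, min(orc$starts))
  }
})

test_that("templates shorter than the primer are reported unanchored", {
  tpl <- tibble::tibble(id = "tiny", sequence = "ACGTACGT",
                        taxon_phylum = "", taxon_class = "",
                        has_flanks = FALSE)
  res <- anchor_primers(tpl, primer_by_name("Bac8f(A)"), maps = NULL)
  expect_false(res$anchored)
  expect_true(is.na(res$n_mismatches))
})
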