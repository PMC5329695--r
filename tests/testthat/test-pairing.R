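test_that("the pair rule table is total, deterministic, and matches the assays", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b19 = bases, b916 = bases, stringsAsFactors = FALSE)
  cls <- classify_pair(grid$b19, grid$b916)
  allowed <- c("native_functional", "nonnative_functional",
               "nonnative_defective", "unknown")
  expect_true(all(cls %in% allowed))
  # exactly the four experimentally tested combinations are non-unknown
  expect_equal(sum(cls != "unknown"), 4)
  expect_identical(classify_pair(grid$b19, grid$b916), cls)  # deterministic
  expect_equal(cls[grid$b19 == "A" & grid$b916 == "T"], "native_functional")
  expect_equal(cls[grid$b19 == "C" & grid$b916 == "G"], "native_functional")
  expect_equal(cls[grid$b19 == "A" & grid$b916 == "G"], "nonnative_functional")
  expect_equal(cls[grid$b19 == "C" & grid$b916 == "T"], "nonnative_defective")
  expect_equal(classify_pair("G", "T"), "unknown")
  # U is accepted as the RNA spelling of T
  expect_equal(classify_pair("C", "U"), "nonnative_defective")
  expect_equal(classify_pair(NA, "T"), "absent")
  expect_equal(classify_pair("A", "-"), "absent")
  expect_error(classify_pair("R", "T"), "ambiguous")
})

test_that("template pair states read through the coordinate map", {
  # reference-like gamma template: 19A-916U native
  tpl <- ref_template()
  maps <- build_coordinate_maps(tpl)
  st <- template_pair_states(tpl, maps)
  focus <- st[st$is_focus, ]
  expect_equal(focus$base_a, "A")
  expect_equal(focus$base_b, "T")
  expect_equal(focus$pair_class, "native_functional")
  # the non-focus h2 pairs are annotated geometrically, never classified
  nonfocus <- st[!st$is_focus, ]
  expect_setequal(nonfocus$pos_a, c(17, 18))
  expect_true(all(nonfocus$pair_class %in%
                    c("watson_crick", "wobble", "mispair", "absent")))
  expect_equal(nonfocus$pair_class, c("watson_crick", "watson_crick"))
})

test_that("beta-like templates carry the native C-G pair", {
  beta <- ref_template("beta")
  beta$sequence <- plant_base(plant_base(beta$sequence, 19, "C"), 916, "G")
  maps <- build_coordinate_maps(beta)
  focus <- template_pair_states(beta, maps) |> dplyr::filter(.data$is_focus)
  expect_equal(focus$pair_class, "native_functional")
})

test_that("templates truncated before 916 report an absent pair state", {
  frag <- ref_template("frag5p")
  frag$sequence <- substr(frag$sequence, 1, 600)
  maps <- build_coordinate_maps(frag)
  focus <- template_pair_states(frag, maps) |> dplyr::filter(.data$is_focus)
  expect_equal(focus$pair_class, "absent")
  expect_true(is.na(focus$base_b))
})

test_that("Bac8f(A) on a beta-like template creates the A-G artifact", {
  beta <- ref_template("beta")
  beta$sequence <- plant_base(plant_base(beta$sequence, 19, "C"), 916, "G")
  maps <- build_coordinate_maps(beta)
  pred <- predict_amplicons(beta, primer_by_name("Bac8f(A)"),
                            primer_by_name("UN1542r"), maps)
  expect_true(pred$amplifiable)
  subs <- pred$substitutions[[1]]
  expect_true(any(subs$ecoli_pos == 19 & subs$template_base == "C" &
                    subs$imposed_base == "A"))
  expect_equal(pred$focus_before, "native_functional")
  expect_equal(pred$focus_after, "nonnative_functional")
  expect_equal(pred$risk_flag, "artifact_functional")
})

test_that("Bac8f(C) on a gamma-like template creates the defective C-U pair", {
  tpl <- ref_template()  # 19A-916T
  maps <- build_coordinate_maps(tpl)
  pred <- predict_amplicons(tpl, primer_by_name("Bac8f(C)"),
                            primer_by_name("UN1542r"), maps)
  subs <- pred$substitutions[[1]]
  expect_true(any(subs$ecoli_pos == 19 & subs$template_base == "A" &
                    subs$imposed_base == "C"))
  expect_equal(pred$focus_after, "nonnative_defective")
  expect_equal(pred$risk_flag, "artifact_defective")
})

test_that("the Bac1f/UN1542r pair never alters any pair state", {
  gb <- gb_corpus()
  pred <- predict_amplicons(gb$templates, primer_by_name("Bac1f"),
                            primer_by_name("UN1542r"), gb$maps)
  ok <- pred$amplifiable
  expect_true(all(ok))
  expect_true(all(pred$risk_flag == "none"))
  expect_identical(pred$focus_after[ok], pred$focus_before[ok])
  # no substitution at any registry site, ever
  reg_pos <- c(17, 18, 19, 916, 917, 918, 1527)
  for (s in pred$substitutions) {
    expect_false(any(s$ecoli_pos %in% reg_pos))
  }
})

test_that("amplicon prediction is idempotent", {
  beta <- ref_template("beta")
  beta$sequence <- plant_base(plant_base(beta$sequence, 19, "C"), 916, "G")
  maps <- build_coordinate_maps(beta)
  fwd <- primer_by_name("Bac8f(A)")
  rev <- primer_by_name("UN1542r")
  pred <- predict_amplicons(beta, fwd, rev, maps)
  amp <- tibble::tibble(id = "amp", sequence = pred$amplicon_seq,
                        taxon_phylum = "", taxon_class = "",
                        has_flanks = FALSE)
  maps2 <- build_coordinate_maps(amp)
  pred2 <- predict_amplicons(amp, fwd, rev, maps2)
  expect_equal(pred2$n_substitutions, 0)
  expect_equal(pred2$risk_flag, "none")
})

test_that("a primer avoiding all registry sites can never flip a pair state", {
  gb <- gb_corpus()
  # footprint 30-47: overlaps no registry position by construction
  ref <- ecoli_like_reference()
  p <- primer_set("interior", substr(ref, 30, 47), "forward",
                  footprint_start = 30L, footprint_end = 47L)
  pred <- predict_amplicons(gb$templates, p, primer_by_name("UN1542r"),
                            gb$maps, window = 100L)
  done <- pred$amplifiable
  expect_identical(pred$focus_after[done], pred$focus_before[done])
  expect_true(all(pred$risk_flag[done] == "none"))
})

test_that("unanchorable primers mark the template not amplifiable", {
  frag <- ref_template("frag3p")
  frag$sequence <- substr(frag$sequence, 1200, 1542)  # no 5' end at all
  maps <- build_coordinate_maps(frag)
  pred <- predict_amplicons(frag, primer_by_name("Bac1f"),
                            primer_by_name("UN1542r"), maps, window = 30L)
  # the 18-mer still places somewhere in a long window, so use the strict
  # short-window case: a template shorter than the primer
  tiny <- tibble::tibble(id = "tiny", sequence = "ACGTACGTACGT",
                         taxon_phylum = "", taxon_class = "",
                         has_flanks = FALSE)
  mt <- build_coordinate_maps(tiny)
  pt <- predict_amplicons(tiny, primer_by_name("Bac8f(A)"),
                          primer_by_name("UN1542r"), mt)
  expect_false(pt$amplifiable)
  expect_equal(pt$risk_flag, "not_amplifiable")
})

test_that("audit verdicts match the primer-design rationale", {
  mix <- mix_corpus()
  prof5 <- composition_profile(mix$templates, mix$maps, c(1, 40))
  prof3 <- composition_profile(mix$templates, mix$maps, c(1500, 1542))
  a_bac8 <- audit_primer(primer_by_name("Bac8f(A)"), prof5)
  expect_equal(a_bac8$verdict, "unsafe")
  expect_equal(a_bac8$offending_positions, 19L)
  a_bac1 <- audit_primer(primer_by_name("Bac1f"), prof5)
  expect_equal(a_bac1$verdict, "safe")
  a_1541 <- audit_primer(primer_by_name("UN1541r(U)"), prof3)
  expect_equal(a_1541$verdict, "unsafe")
  expect_equal(a_1541$offending_positions, 1527L)
  a_1542 <- audit_primer(primer_by_name("UN1542r"), prof3)
  expect_equal(a_1542$verdict, "safe")
  # broom-style accessors
  expect_equal(glance(a_bac8)$verdict, "unsafe")
  expect_true(all(c("ecoli_pos", "offending") %in% names(tidy(a_bac8))))
})
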