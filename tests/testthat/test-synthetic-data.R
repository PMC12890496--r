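test_that("identical spec and seed reproduce identical tables", {
  s1 <- generate_study(tiny_spec(seed = 11))
  s2 <- generate_study(tiny_spec(seed = 11))
  expect_identical(s1$train, s2$train)
  expect_identical(s1$val, s2$val)
  expect_identical(s1$meta, s2$meta)
  s3 <- generate_study(tiny_spec(seed = 12))
  expect_false(identical(s1$train, s3$train))
})

test_that("spec validation rejects inconsistent inputs", {
  expect_error(tiny_spec(marker_panels = list(train = c("A", "B"),
                                              val = c("C", "D"))),
               "share no markers")
  expect_error(tiny_spec(cells_per_donor = c(train = 0, val = 300)),
               "positive")
  expect_error(subpop_template("x", "NK", c(CD57 = 3), baseline_freq = 0.6,
                               effect = c(EOMG = 2)),
               "must not exceed 1")
  expect_error(tiny_spec(lineage_mixture = c(B = 0.5, CD4T = 0.2)),
               "summing to 1")
  expect_error(tiny_spec(mait_fraction = 1.2), "probability")
})

test_that("unity effects leave group frequencies balanced", {
  spec <- tiny_spec(n_train = c(EOMG = 70, LOMG = 70, CTRL = 60),
                    n_val = c(EOMG = 2, LOMG = 2, CTRL = 0),
                    cells_per_donor = c(train = 400, val = 100),
                    subpop_templates = mg_subpop_templates(effect_low = 1),
                    n_thymus = c(EOMG = 1, LOMG = 0),
                    thymus_cells_per_donor = 100,
                    seed = 21)
  study <- generate_study(spec)
  blood <- study$train[study$train$tissue == "blood", ]
  grp <- setNames(study$meta$group, study$meta$donor_id)
  for (tpl in c("CD8T_naive", "CD8T_mait", "NK_cd57")) {
    lin <- if (tpl == "NK_cd57") "NK" else "CD8T"
    f <- vapply(split(blood, blood$donor_id), function(d) {
      sum(d$true_subpop == tpl) / max(1, sum(d$lineage == lin))
    }, 0)
    g <- grp[names(f)]
    delta <- mean(f[g == "EOMG"]) - mean(f[g == "LOMG"])
    se <- sqrt(var(f[g == "EOMG"]) / sum(g == "EOMG") +
                 var(f[g == "LOMG"]) / sum(g == "LOMG"))
    expect_lt(abs(delta), 3 * se)
  }
})

test_that("negative hyperplasia link produces negative grade correlation", {
  tpls <- mg_subpop_templates()
  tpls[[3]]$effect["EOMG"] <- 0.3
  spec <- tiny_spec(n_train = c(EOMG = 50, LOMG = 4, CTRL = 4),
                    cells_per_donor = c(train = 500, val = 100),
                    n_val = c(EOMG = 2, LOMG = 2, CTRL = 0),
                    subpop_templates = tpls,
                    n_thymus = c(EOMG = 50, LOMG = 0),
                    thymus_cells_per_donor = 100,
                    hyperplasia_link = -1.2,
                    seed = 31)
  study <- generate_study(spec)
  meta <- study$meta
  thy <- meta[meta$has_thymus, ]
  expect_true(all(thy$hyperplasia_grade %in% 0:3))
  blood <- study$train[study$train$tissue == "blood", ]
  f <- vapply(split(blood, blood$donor_id), function(d) {
    100 * sum(d$true_subpop == "NK_cd57") / max(1, sum(d$lineage == "NK"))
  }, 0)
  r <- cor(log10(f[thy$donor_id] + 0.01), thy$hyperplasia_grade)
  expect_lt(r, 0)
})

test_that("lineage counts follow the multinomial mixture", {
  spec <- tiny_spec(cells_per_donor = c(train = 2000, val = 100), seed = 41)
  study <- generate_study(spec)
  blood <- study$train[study$train$tissue == "blood", ]
  obs <- table(factor(blood$lineage, names(spec$lineage_mixture)))
  gof <- suppressWarnings(
    chisq.test(obs, p = spec$lineage_mixture[names(obs)]))
  expect_gt(gof$p.value, 0.001)
})

test_that("repertoire respects the invariant TCR-alpha boundary cases", {
  spec <- tiny_spec(mait_fraction = 0, mait_background = 0, seed = 51)
  study <- generate_study(spec)
  rep0 <- generate_repertoire(spec, study$train, seed = 1)
  expect_equal(sum(rep0$v_alpha == "Va7.2" & rep0$j_alpha == "Ja33"), 0)

  # forced singleton clones give zero clonality
  tpls <- lapply(mg_subpop_templates(), function(t) {
    t$clone_param <- 1
    t
  })
  spec1 <- tiny_spec(subpop_templates = tpls, clone_size_param = 1,
                     seed = 52)
  study1 <- generate_study(spec1)
  rep1 <- generate_repertoire(spec1, study1$train, seed = 1)
  expect_equal(clonality_fraction(rep1), 0)

  expect_error(generate_repertoire(
    spec, study$train[study$train$lineage != "CD8T", ]), "CD8T")
})

test_that("the MAIT-like template carries the invariant pair at its rate", {
  spec <- tiny_spec(n_train = c(EOMG = 10, LOMG = 10, CTRL = 10),
                    cells_per_donor = c(train = 2000, val = 100),
                    mait_fraction = 0.26, seed = 61)
  study <- generate_study(spec)
  reper <- generate_repertoire(spec, study$train, seed = 2)
  blood <- study$train
  mait_ids <- blood$cell_id[blood$true_subpop == "CD8T_mait"]
  sub <- reper[reper$cell_id %in% mait_ids, ]
  n_obs <- sum(sub$v_alpha == "Va7.2" & sub$j_alpha == "Ja33")
  ci <- qbinom(c(0.005, 0.995), nrow(sub), 0.26)
  expect_gte(n_obs, ci[1])
  expect_lte(n_obs, ci[2])
  # repertoire is reproducible under an explicit seed
  rep2 <- generate_repertoire(spec, study$train, seed = 2)
  expect_identical(reper, rep2)
})

test_that("cell tables round-trip through CSV", {
  study <- generate_study(tiny_spec(cells_per_donor = c(train = 50,
                                                        val = 50),
                                    seed = 71))
  path <- tempfile(fileext = ".csv")
  write_cell_table(study$val, path)
  back <- read_cell_table(path)
  expect_equal(back$cell_id, study$val$cell_id)
  expect_equal(marker_matrix(back), marker_matrix(study$val),
               tolerance = 1e-12, ignore_attr = TRUE)
  unlink(path)
})
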