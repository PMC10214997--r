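# small catalog (5-cm thickness only) on the coarse phantom keeps these fast
coarse_engine <- function(case = "wide_disk") {
  plan_engine(coarse_phantom(case), fix_beam, fix_tissues, fix_grid)
}

test_that("select_best maximizes the minimum tumor dose with documented tie-breaks", {
  cands <- data.frame(config_id = c("a", "b"), d_min_tumor = c(21.0, 25.9),
                      HI = c(0.84, 0.54), time_min = c(67, 93))
  expect_equal(select_best(cands)$best$config_id, "b")
  ties <- data.frame(config_id = c("x", "y", "z"),
                     d_min_tumor = c(10, 10, 10),
                     HI = c(0.6, 0.5, 0.5), time_min = c(30, 40, 20))
  expect_equal(select_best(ties)$best$config_id, "z")
  single <- cands[1, ]
  expect_equal(select_best(single)$best$config_id, "a")
  expect_error(select_best(cands[0, ]), "empty")
})

test_that("evaluate_all produces one candidate per configuration and ratio", {
  eng <- coarse_engine()
  cat5 <- build_catalog(fix_grid, 5)
  cands <- evaluate_all(cat5, ratios = c(2, 5), engine = eng)
  expect_equal(nrow(cands), 106 * 2)
  expect_s3_class(cands, "plan_candidates")
  expect_true(all(cands$d_min_tumor >= 0))
  expect_true(all(cands$limiting_tissue %in% c("skin", "brain")))

  one <- cat5
  one$configs <- one$configs[5, , drop = FALSE]
  expect_equal(nrow(evaluate_all(one, ratios = 3, engine = eng)), 1)
  expect_error(evaluate_all(cat5, ratios = integer(0), engine = eng),
               "non-empty")
})

test_that("candidate evaluation is deterministic across runs", {
  cat5 <- build_catalog(fix_grid, 5)
  c1 <- evaluate_all(cat5, ratios = 2, engine = coarse_engine())
  c2 <- evaluate_all(cat5, ratios = 2, engine = coarse_engine())
  expect_identical(c1, c2)
})

test_that("fast engine agrees with the full-map plan computation", {
  ph <- coarse_phantom("small_rect")
  eng <- plan_engine(ph, fix_beam, fix_tissues, fix_grid)
  cat5 <- build_catalog(fix_grid, 5)
  shape <- cat5$shapes[["C2-01"]]
  cands <- evaluate_all(cat5, ratios = 4, engine = eng)
  row <- cands[cands$shape_id == "C2-01", ]
  full <- plan_doses(if_a_pattern(), shape_to_pattern(shape, 5), 4, ph,
                     fix_beam, fix_tissues, fix_grid)
  expect_equal(row$time_min, full$time_min, tolerance = 1e-10)
  expect_equal(row$d_min_tumor, full$d_min_tumor, tolerance = 1e-10)
  expect_equal(row$HI, full$HI, tolerance = 1e-10)
})

test_that("the baseline is the IF-A-only plan at full prescription", {
  base <- baseline_plan(engine = coarse_engine())
  expect_equal(base$config_id, "IF-A")
  sat <- min(abs(base$skin_max - 12) / 12, abs(base$brain_max - 15) / 15)
  expect_lt(sat, 1e-9)
})

test_that("the selected plan dominates the baseline on the coarse wide tumor", {
  eng <- coarse_engine()
  cands <- evaluate_all(build_catalog(fix_grid, 5), ratios = c(2, 3, 4, 5),
                        engine = eng)
  base <- baseline_plan(engine = eng)
  res <- select_best(cands, base)
  expect_true(all(res$best$d_min_tumor >= cands$d_min_tumor))
  expect_gt(res$best$d_min_tumor, base$d_min_tumor)
  expect_gte(as.numeric(improvement_percent(base$HI, res$best$HI)), 0)
})

test_that("sensitivity sweeps move the minimum tumor dose in the right direction", {
  ph <- coarse_phantom("small_rect")
  eng <- plan_engine(ph, fix_beam, fix_tissues, fix_grid)
  cat5 <- build_catalog(fix_grid, 5)
  res <- select_best(evaluate_all(cat5, ratios = c(2, 5), engine = eng),
                     baseline_plan(engine = eng))
  boron <- sensitivity_sweep(res, "blood_boron", values = c(10, 20, 30, 40),
                             phantom = ph, beam = fix_beam,
                             tissues = fix_tissues, grid = fix_grid,
                             catalog = cat5)
  for (p in c("baseline", "optimized")) {
    expect_true(all(diff(boron$d_min_tumor[boron$plan == p]) >= 0), label = p)
  }
  sb <- sensitivity_sweep(res, "skin_blood_ratio",
                          values = seq(1.0, 1.5, by = 0.1),
                          phantom = ph, beam = fix_beam,
                          tissues = fix_tissues, grid = fix_grid,
                          catalog = cat5)
  for (p in c("baseline", "optimized")) {
    expect_true(all(diff(sb$d_min_tumor[sb$plan == p]) <= 1e-12), label = p)
  }
  expect_error(
    sensitivity_sweep(res, "blood_boron", values = c(-5, 10), phantom = ph,
                      beam = fix_beam, tissues = fix_tissues,
                      grid = fix_grid, catalog = cat5),
    "positive")
})

test_that("the limiting tissue can switch, giving a brain-limited plateau", {
  # with a brain-avid boron distribution the brain limit binds at low S/B:
  # the minimum tumor dose stays flat until skin takes over
  ph <- coarse_phantom("small_rect")
  tiss <- tissue_model(brain_blood_ratio = 3)
  eng <- plan_engine(ph, fix_beam, tiss, fix_grid)
  cat5 <- build_catalog(fix_grid, 5)
  res <- select_best(evaluate_all(cat5, ratios = 2, engine = eng),
                     baseline_plan(engine = eng))
  sw <- sensitivity_sweep(res, "skin_blood_ratio",
                          values = seq(0.4, 1.6, by = 0.2), phantom = ph,
                          beam = fix_beam, tissues = tiss, grid = fix_grid,
                          catalog = cat5)
  base_sw <- sw[sw$plan == "baseline", ]
  expect_true(all(c("brain", "skin") %in% base_sw$limiting_tissue))
  flat <- base_sw$d_min_tumor[base_sw$limiting_tissue == "brain"]
  expect_lt(diff(range(flat)), 1e-9)
  falling <- base_sw$d_min_tumor[base_sw$limiting_tissue == "skin"]
  expect_true(all(diff(falling) < 0))
})
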