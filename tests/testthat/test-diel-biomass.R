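test_that("lipid species partition into droplet and bulk lipid", {
  tags <- c("tag_a", "tag_b", "tag_c")
  others <- c("mgdg", "dgdg", "pe", "pg", "sqdg")
  out <- split_lipids(c(tags, others), tags)
  expect_equal(sum(out$component == "lipid_droplet"), 3)
  expect_equal(sum(out$component == "lipid"), 5)
  # duplicates deduplicated
  out2 <- split_lipids(c(tags, others), c(tags, tags[1]))
  expect_equal(sum(out2$component == "lipid_droplet"), 3)
  # empty TAG list: droplet pool empty, flagged
  out3 <- split_lipids(others, character(0))
  expect_true(all(out3$component == "lipid"))
  expect_true(isTRUE(attr(out3, "empty_droplet")))
})

test_that("biomass split creates 10 synthesis + 10 degradation reactions", {
  toy <- toy_fixture()
  dm <- split_biomass(toy$model, toy$component_map)
  expect_equal(nrow(dm$components), 10)
  expect_setequal(dm$components$component, biomass_components())
  rx <- dm$model$reactions$id
  expect_equal(sum(grepl("^SYNC_", rx)), 10)
  expect_equal(sum(grepl("^DEGC_", rx)), 10)
  # original biomass reaction disabled
  j <- match("BIOMASS", rx)
  expect_equal(dm$model$reactions$lb[j], 0)
  expect_equal(dm$model$reactions$ub[j], 0)
})

test_that("component syntheses at mass fractions reproduce the biomass", {
  toy <- toy_fixture()
  dm <- split_biomass(toy$model, toy$component_map)
  orig <- toy$model$S[, "BIOMASS"]
  recon <- rep(0, length(orig))
  names(recon) <- names(orig)
  for (r in seq_len(nrow(dm$components))) {
    recon <- recon + dm$model$S[, dm$components$syn_id[r]] *
      dm$components$mass_fraction[r]
  }
  expect_equal(recon, orig, tolerance = 1e-12)
  # mass fractions sum to 1 (the toy biomass is exactly 1 g per gDW)
  expect_equal(sum(dm$components$mass_fraction), 1, tolerance = 1e-9)
  # unit synthesis flux forms 1 g of component: coefficient x MW sums to 1 g
  mw <- stats::setNames(formula_weight(dm$model$metabolites$formula),
                        dm$model$metabolites$id)
  for (r in seq_len(nrow(dm$components))) {
    col <- dm$model$S[, dm$components$syn_id[r]]
    consumed <- -col[col < 0]
    expect_equal(sum(consumed * mw[names(consumed)]) / 1000, 1,
                 tolerance = 1e-9, label = dm$components$component[r])
  }
})

test_that("biomass split validates its component map", {
  toy <- toy_fixture()
  map <- toy$component_map
  expect_error(split_biomass(toy$model, map[-1, ]), "not assigned")
  bad <- rbind(map, tibble::tibble(metabolite = "co2", component = "starch"))
  expect_error(split_biomass(toy$model, bad), "not consumed")
  dup <- rbind(map, map[1, ])
  expect_error(split_biomass(toy$model, dup), "exactly one")
  odd <- map; odd$component[1] <- "mystery_pool"
  expect_error(split_biomass(toy$model, odd), "unknown component")
})

test_that("PI controllers integrate error and clamp at the windup box", {
  st <- new_controller_state(c("starch", "protein"), kp = 1, ki = 0.1)
  sp <- c(starch = 0.2, protein = 0.4)
  # on-setpoint history: all errors zero
  st0 <- update_controllers(st, sp, sp, dt = 0.1)
  expect_equal(st0$e_prod, c(0, 0))
  expect_equal(st0$e_cons, c(0, 0))
  # held 10% above setpoint: consumption error grows, then saturates
  x <- c(starch = 0.3, protein = 0.4)
  prev <- -Inf
  for (i in 1:30) {
    st <- update_controllers(st, x, sp, dt = 1)
    expect_gte(st$e_cons[1], prev - 1e-12)
    prev <- st$e_cons[1]
  }
  expect_gt(st$e_cons[1], 0)
  expect_equal(st$integral[1], -st$windup_factor[1] * sp[["starch"]])
  # e_cons is the negative of e_prod by construction
  expect_equal(st$e_cons, -st$e_prod)
  # Ki = 0: purely proportional, memoryless
  stp <- new_controller_state("starch", kp = 2, ki = 0)
  stp <- update_controllers(stp, c(starch = 0.25), c(starch = 0.2), dt = 1)
  stp <- update_controllers(stp, c(starch = 0.25), c(starch = 0.2), dt = 1)
  expect_equal(stp$e_cons, 2 * 0.05)
})

test_that("objective weights normalize positive errors", {
  e <- c(a = 2, b = 1, c = 0, d = -3)
  w <- objective_weights(e)
  expect_equal(unname(w[c("a", "b")]), c(2 / 3, 1 / 3))
  expect_equal(unname(w[c("c", "d")]), c(0, 0))
  expect_equal(sum(w), 1)
  # single producible component takes all weight
  expect_equal(unname(objective_weights(e, producible = "a")), 1)
  # all at setpoint: uniform over producible
  z <- objective_weights(c(a = 0, b = 0), producible = c("a", "b"))
  expect_equal(unname(z), c(0.5, 0.5))
  # all strongly above setpoint: nothing produced
  none <- objective_weights(c(a = -1, b = -2))
  expect_length(none, 0)
})

test_that("consumption priority orders positive errors, emergency appends", {
  e <- c(starch = 5, protein = 1, lipid = -2)
  expect_equal(consumption_priority(e), c("starch", "protein"))
  full <- consumption_priority(e, ngam_unmet = TRUE)
  expect_equal(as.character(full), c("starch", "protein", "lipid"))
  # all negative with NGAM unmet: full descending list, flagged
  e2 <- c(protein = -1, starch = -1, lipid = -3)
  full2 <- consumption_priority(e2, ngam_unmet = TRUE)
  expect_true(attr(full2, "emergency"))
  # exact tie between starch and protein: starch promoted
  expect_equal(as.character(full2), c("starch", "protein", "lipid"))
  expect_length(consumption_priority(e2, ngam_unmet = FALSE), 0)
  # deterministic tie-break by canonical order for positives
  e3 <- c(starch = 2, protein = 2)
  expect_equal(consumption_priority(e3), c("protein", "starch"))
})

test_that("setpoint interpolation is periodic and validates totals", {
  sp <- toy_fixture()$setpoints
  f <- setpoint_fn(sp)
  expect_equal(f(0), f(24), tolerance = 1e-12)
  expect_equal(f(6)[["starch"]], (0.15 + 0.30) / 2, tolerance = 1e-9)
  expect_equal(sum(f(7.3)), 1, tolerance = 1e-9)
  bad <- sp; bad$fraction[bad$component == "protein"] <- 0.9
  expect_error(setpoint_fn(bad), "more than 1")
})
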