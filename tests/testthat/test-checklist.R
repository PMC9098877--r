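test_that("name reconciliation normalises whitespace and case, collapses synonyms", {
  backbone <- tibble::tibble(
    input_name = c("Inga edulis", "Inga vera", "Inga falsa"),
    accepted_name = c("Inga edulis Mart.", "Inga vera Willd.",
                      "Inga vera Willd."),
    taxon_id = c("t1", "t2", "t2"),
    match_status = c("accepted", "accepted", "synonym"))
  res <- reconcile_names(c("Inga edulis", "Inga  edulis ", "INGA FALSA",
                           "Xyzus fakeus"), backbone)
  expect_equal(nrow(res$mapping), 3)
  expect_equal(unique(res$mapping$taxon_id[1:2]), "t1")
  expect_equal(res$mapping$taxon_id[res$mapping$input_name == "INGA FALSA"],
               "t2")
  expect_equal(res$unmatched, "Xyzus fakeus")
  # distinct taxa after synonym collapse
  expect_equal(dplyr::n_distinct(res$mapping$taxon_id), 2)
})

test_that("reconciliation errors on conflicting backbone duplicates and reports unmatched-status rows", {
  conflict <- tibble::tibble(
    input_name = c("Inga edulis", "inga  edulis"),
    accepted_name = c("Inga edulis Mart.", "Inga oerstediana Benth."),
    taxon_id = c("t1", "t9"), match_status = "accepted")
  expect_error(reconcile_names("Inga edulis", conflict), "conflicting")

  unm <- tibble::tibble(input_name = "Mystery plant", accepted_name = "",
                        taxon_id = "", match_status = "unmatched")
  res <- reconcile_names("Mystery plant", unm)
  expect_equal(nrow(res$mapping), 0)
  expect_equal(res$unmatched, "Mystery plant")
})

test_that("reconciliation is idempotent on accepted names and recovers generator synonymy", {
  cfg <- scenario_config(seed = 11, n_species = 50, synonym_rate = 0.2)
  chk <- simulate_checklist(cfg)
  # verbatim names (with synonyms) all resolve, none unmatched
  res <- reconcile_names(chk$verbatim_names, chk$backbone)
  expect_length(res$unmatched, 0)
  expect_equal(sort(unique(res$mapping$taxon_id)),
               sort(chk$checklist$taxon_id))
  # synonym map agrees with the answer key
  key <- chk$answer_key$synonym_map
  for (syn in names(key)) {
    expect_equal(
      res$mapping$accepted_name[res$mapping$input_name == syn], key[[syn]])
  }
  # idempotence: feeding accepted names back returns identity
  res2 <- reconcile_names(chk$checklist$accepted_name, chk$backbone)
  expect_equal(res2$mapping$input_name, res2$mapping$accepted_name)
  expect_length(res2$unmatched, 0)
})

test_that("NUS flagging partitions the checklist against the crop census", {
  chk <- toy_checklist()
  out <- flag_nus(chk, c("Genus1 b", "Genus4 e"))
  expect_equal(sum(out$is_nus), 4)
  expect_true(all(out$is_nus == !out$in_crop_census))
  # empty census: everything NUS
  out0 <- flag_nus(chk, character())
  expect_true(all(out0$is_nus))
  # generator answer key
  cfg <- scenario_config(seed = 3, n_species = 200,
                         crop_census_fraction = 17 / 200)
  sim <- simulate_checklist(cfg)
  flagged <- flag_nus(sim$checklist, sim$crops$accepted_name)
  expect_equal(sum(flagged$is_nus), sim$answer_key$n_nus)
  expect_equal(sum(flagged$is_nus), 200 - nrow(sim$crops))
  expect_equal(sum(flagged$is_nus) + sum(flagged$in_crop_census), 200)
})

test_that("percentage shares use round-half-away-from-zero to one decimal", {
  expect_equal(compute_share(3132, 3805), 82.3)
  expect_equal(compute_share(146, 3805), 3.8)
  expect_equal(compute_share(0, 3805), 0.0)
  expect_equal(compute_share(3805, 3805), 100.0)
  # half-away-from-zero at the .x5 boundary: 0.25% of 1000 -> 2.5 -> wait,
  # 25/1000 = 2.5 exactly, rounds up to 2.5; 5/1000 = 0.5 -> 0.5
  expect_equal(compute_share(1, 16), 6.3)   # 6.25 rounds away to 6.3
  expect_equal(compute_share(3, 16), 18.8)  # 18.75 -> 18.8
  expect_error(compute_share(1, 0), "positive")
  expect_error(compute_share(5, 3))
  # monotone in k
  ks <- 0:50
  expect_true(all(diff(compute_share(ks, 50)) >= 0))
})

test_that("catalogue summary counts flags and distinct taxa; shares recompute", {
  s <- summarize_catalogue(toy_checklist())
  expect_equal(unname(s$counts[c("n_species", "n_families", "n_genera")]),
               c(6, 3, 4))
  expect_equal(unname(s$counts[c("n_native", "n_endemic", "n_naturalised",
                                 "n_cultivated")]), c(4, 1, 2, 2))
  expect_equal(s$counts[["n_locally_reported"]] +
                 s$counts[["n_not_locally_reported"]],
               s$counts[["n_species"]])
  expect_true(all(s$counts <= s$counts[["n_species"]]))
  expect_equal(unname(s$shares["pct_endemic"]), compute_share(1, 6))
  expect_error(summarize_catalogue(toy_checklist()[0, ]), "empty")

  # generator flag counts recovered
  cfg <- scenario_config(seed = 5, n_species = 500)
  sim <- simulate_checklist(cfg)
  s2 <- summarize_catalogue(flag_nus(sim$checklist,
                                     sim$crops$accepted_name))
  key <- sim$answer_key
  expect_equal(s2$counts[["n_native"]], key$flag_counts$native)
  expect_equal(s2$counts[["n_endemic"]], key$flag_counts$endemic)
  expect_equal(s2$counts[["n_nus"]], key$n_nus)
  expect_equal(s2$counts[["n_families"]], key$n_families)
  expect_equal(s2$counts[["n_genera"]], key$n_genera)
  # endemic implies native in every draw
  expect_true(all(!sim$checklist$endemic | sim$checklist$native))
})

test_that("family ranking sorts by genus then species count then name, and matches a recount oracle", {
  r <- rank_families(toy_checklist(), n = 10)
  expect_equal(r$family, c("FamA", "FamC", "FamB"))
  expect_equal(r$n_genera, c(2, 1, 1))
  expect_equal(r$n_species, c(3, 2, 1))
  # n larger than family count returns all; native restriction recounts
  expect_equal(nrow(rank_families(toy_checklist(), n = 99)), 3)
  rn <- rank_families(toy_checklist(), n = 3, native_only = TRUE)
  expect_equal(rn$n_species[rn$family == "FamA"], 2)
  # totals conserve species and genus counts
  cfg <- scenario_config(seed = 9, n_species = 400)
  sim <- simulate_checklist(cfg)
  full <- rank_families(sim$checklist, n = 1e6)
  expect_equal(sum(full$n_species), 400)
  expect_equal(sum(full$n_genera),
               nrow(unique(sim$checklist[, c("family", "genus")])))
  # brute-force recount on one family
  fam <- full$family[1]
  sub <- sim$checklist[sim$checklist$family == fam, ]
  expect_equal(full$n_genera[1], length(unique(sub$genus)))
  expect_equal(full$n_species[1], nrow(sub))
})

test_that("genus-by-habit ranking uses set semantics over pipe-separated habits", {
  chk <- toy_checklist()
  r <- rank_genera_by_habit(chk, "tree", n = 5)
  expect_equal(r$genus[1], "Genus1")          # two tree species
  expect_equal(r$n_species, c(2, 1))          # Genus1, Genus4
  # t2 has tree|shrub: counted once under each habit
  rs <- rank_genera_by_habit(chk, "shrub", n = 5)
  expect_true("Genus1" %in% rs$genus)
  expect_warning(parse_habits("liana"), "other")
})
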