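test_that("an in-window mobile exposed cross-domain pair is selected; out-of-window is not", {
  # pair 1: d_closed 10.5 -> 14.0 (selected, delta 3.5)
  # pair 2: d_closed 5.0 -> 9.0 (rejected by the distance window despite
  #         passing every other predicate)
  closed <- cb_atoms(c("A", "B", "A", "B"), c(1, 1, 2, 2),
                     rbind(c(0, 0, 0), c(10.5, 0, 0),
                           c(0, 80, 0), c(5, 80, 0)))
  open <- cb_atoms(c("A", "B", "A", "B"), c(1, 1, 2, 2),
                   rbind(c(0, 0, 0), c(14, 0, 0),
                         c(0, 80, 0), c(9, 80, 0)))
  path <- write_test_pdb(closed, models = list(closed, open))
  ens <- read_structure(path, labels = c("closed", "open"))
  domains <- list(domain_definition("propeller", "A", 1, 10),
                  domain_definition("peptidase", "B", 1, 10))
  pairs <- select_pairs(ens, domains, design_config())
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$res_i, 1)
  expect_equal(pairs$chain_j, "B")
  expect_equal(pairs$delta, 3.5, tolerance = 1e-6)
  expect_equal(pairs$d_closed, 10.5, tolerance = 1e-6)
})

test_that("same-domain pairs and buried residues are rejected", {
  closed <- cb_atoms(c("A", "A"), c(1, 2), rbind(c(0, 0, 0), c(10.5, 0, 0)))
  open <- cb_atoms(c("A", "A"), c(1, 2), rbind(c(0, 0, 0), c(14, 0, 0)))
  ens <- read_structure(write_test_pdb(closed, models = list(closed, open)),
                        labels = c("closed", "open"))
  # both residues in one domain -> nothing survives the cross-domain rule
  one_dom <- list(domain_definition("propeller", "A", 1, 10))
  expect_equal(nrow(select_pairs(ens, one_dom, design_config())), 0)
  # an exposure threshold above anything attainable rejects everything
  two_dom <- list(domain_definition("propeller", "A", 1, 1),
                  domain_definition("peptidase", "A", 2, 2))
  cfg <- design_config(min_relative_sasa = 1.0)
  got <- select_pairs(ens, two_dom, cfg)
  rs <- closed_state_rsasa(ens, cfg)
  expect_equal(nrow(got), sum(rs[1] >= 1 & rs[2] >= 1))
})

test_that("uncovered residues raise a configuration error", {
  closed <- cb_atoms(c("A", "B"), c(1, 1), rbind(c(0, 0, 0), c(10.5, 0, 0)))
  ens <- read_structure(write_test_pdb(closed, models = list(closed, closed)),
                        labels = c("closed", "open"))
  expect_error(
    select_pairs(ens, list(domain_definition("propeller", "A", 1, 10)),
                 design_config(min_delta_distance = 0)),
    "not covered")
  expect_error(
    select_pairs(ens, list(domain_definition("a", "A", 1, 1),
                           domain_definition("b", "B", 1, 1)),
                 design_config(closed_label = "shut")),
    "shut")
})

test_that("selection equals the exhaustive four-predicate oracle on random hinge toys", {
  specs <- list(
    hinge_toy_spec(residues_per_domain = 20, n_planted = 4, seed = 101),
    hinge_toy_spec(residues_per_domain = 25, n_planted = 6, seed = 102,
                   hinge_angle_open = 20),
    hinge_toy_spec(residues_per_domain = 30, n_planted = 5, seed = 103,
                   planted_targets = c(9.6, 10.2, 10.8, 11.4, 12.5)))
  cfgs <- list(design_config(),
               design_config(distance_halfwidth = 0.5,
                             min_delta_distance = 1.0),
               design_config(min_relative_sasa = 0.5))
  for (k in seq_along(specs)) {
    toy <- make_hinge_toy(specs[[k]], dir = tempfile())
    ens <- read_structure(toy$pdb, labels = toy$model_labels)
    cfg <- cfgs[[k]]
    got <- select_pairs(ens, toy$domains, cfg)
    oracle <- brute_force_pairs(ens, toy$domains, cfg,
                                closed_state_rsasa(ens, cfg))
    expect_equal(pair_key(got), pair_key(oracle))
    # ranking: descending delta, ranks a permutation of 1..k
    expect_equal(got$rank, seq_len(nrow(got)))
    expect_true(all(diff(got$delta) <= 1e-12))
  }
})

test_that("ties in delta are broken by ascending residue identifiers", {
  # two symmetric pairs with identical delta
  closed <- cb_atoms(c("A", "A", "B", "B"), c(1, 2, 1, 2),
                     rbind(c(0, 0, 0), c(0, 60, 0),
                           c(10.5, 0, 0), c(10.5, 60, 0)))
  open <- cb_atoms(c("A", "A", "B", "B"), c(1, 2, 1, 2),
                   rbind(c(0, 0, 0), c(0, 60, 0),
                         c(14, 0, 0), c(14, 60, 0)))
  ens <- read_structure(write_test_pdb(closed, models = list(closed, open)),
                        labels = c("closed", "open"))
  pairs <- select_pairs(ens, list(domain_definition("a", "A", 1, 5),
                                  domain_definition("b", "B", 1, 5)),
                        design_config())
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$res_i, c(1, 2))
})

test_that("tightening any threshold never adds pairs", {
  toy <- make_hinge_toy(hinge_toy_spec(residues_per_domain = 25,
                                       n_planted = 6, seed = 77),
                        dir = tempfile())
  ens <- read_structure(toy$pdb, labels = toy$model_labels)
  base <- design_config(distance_halfwidth = 1.5, min_delta_distance = 1,
                        min_relative_sasa = 0.1)
  loose <- pair_key(select_pairs(ens, toy$domains, base))
  tighter <- list(
    design_config(distance_halfwidth = 0.5, min_delta_distance = 1,
                  min_relative_sasa = 0.1),
    design_config(distance_halfwidth = 1.5, min_delta_distance = 4,
                  min_relative_sasa = 0.1),
    design_config(distance_halfwidth = 1.5, min_delta_distance = 1,
                  min_relative_sasa = 0.6))
  for (cfg in tighter) {
    expect_true(all(pair_key(select_pairs(ens, toy$domains, cfg)) %in% loose))
  }
})

test_that("a degenerate hinge (open == closed) yields no pairs when a distance change is required", {
  toy <- make_hinge_toy(hinge_toy_spec(residues_per_domain = 15,
                                       n_planted = 3, hinge_angle_open = 0,
                                       seed = 9),
                        dir = tempfile())
  ens <- read_structure(toy$pdb, labels = toy$model_labels)
  expect_equal(nrow(select_pairs(ens, toy$domains, design_config())), 0)
  # with no delta requirement the planted in-window pairs reappear
  some <- select_pairs(ens, toy$domains,
                       design_config(min_delta_distance = 0))
  expect_gt(nrow(some), 0)
  expect_equal(unique(round(some$delta, 6)), 0)
})

test_that("double-variant counting matches pair enumeration", {
  expect_equal(count_double_variants(616), 189420)
  expect_equal(count_double_variants(2), 1)
  expect_equal(count_double_variants(10), nrow(t(combn(10, 2))))
  expect_error(count_double_variants(1), ">= 2")
  expect_error(count_double_variants(3.5), ">= 2")
})
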