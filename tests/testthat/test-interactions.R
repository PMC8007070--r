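test_that("minimum group distance matches the brute-force scan", {
  atoms <- data.frame(chain = c("A", "A", "B"), resno = c(1, 1, 1),
                      elety = c("X1", "X2", "Y1"))
  frames <- list(rbind(c(0, 0, 0), c(5, 0, 0), c(3, 4, 0)))
  m <- toy_model(atoms, frames)
  p1 <- atom_group_pair("one-vs-one",
                        data.frame(chain = "A", resno = 1, elety = "X1"),
                        data.frame(chain = "B", resno = 1, elety = "Y1"))
  expect_equal(min_group_distance(frame_coords(m), p1, m), 5)
  p2 <- atom_group_pair("two-vs-one",
                        data.frame(chain = "A", resno = 1,
                                   elety = c("X1", "X2")),
                        data.frame(chain = "B", resno = 1, elety = "Y1"))
  expect_equal(min_group_distance(frame_coords(m), p2, m), sqrt(20),
               tolerance = 1e-9)
  # missing atom propagates as not-evaluable, never 0
  p3 <- atom_group_pair("missing",
                        data.frame(chain = "A", resno = 1, elety = "X1"),
                        data.frame(chain = "B", resno = 1, elety = "NOPE"))
  expect_true(is.na(min_group_distance(frame_coords(m), p3, m)))
})

test_that("detection matches an exhaustive pair scan on random toys", {
  set.seed(401)
  for (rep in 1:50) {
    na <- sample(1:6, 1)
    nb <- sample(1:6, 1)
    nf <- sample(1:4, 1)
    atoms <- data.frame(chain = rep(c("A", "B"), c(na, nb)),
                        resno = 1,
                        elety = c(paste0("A", 1:na), paste0("B", 1:nb)))
    frames <- lapply(seq_len(nf), function(i)
      matrix(stats::runif((na + nb) * 3, -6, 6), ncol = 3))
    m <- toy_model(atoms, frames)
    pair <- atom_group_pair("toy",
                            data.frame(chain = "A", resno = 1,
                                       elety = paste0("A", 1:na)),
                            data.frame(chain = "B", resno = 1,
                                       elety = paste0("B", 1:nb)))
    rec <- detect_interaction(m, pair)
    oracle <- vapply(frames, function(f)
      brute_min_dist(f[1:na, , drop = FALSE],
                     f[na + (1:nb), , drop = FALSE]), 1)
    expect_equal(rec$distance_series, oracle, tolerance = 1e-9)
    expect_equal(rec$occupancy, mean(oracle <= 3.5))
  }
})

test_that("group swap leaves the distance series unchanged", {
  tc <- fixture_template()
  pair <- fixture_saltbridge_pair()
  swapped <- atom_group_pair(pair$label, pair$group_b, pair$group_a,
                             kind = pair$kind)
  ens <- sample_ensemble(synthetic_ensemble_spec(
    tc, 50, seed = 9, contacts = list(contact_spec(pair, 0.5))))$model
  expect_equal(detect_interaction(ens, pair)$distance_series,
               detect_interaction(ens, swapped)$distance_series)
})

test_that("single-frame stability follows the distance cutoffs", {
  mk <- function(d, kind) {
    atoms <- data.frame(chain = c("A", "B"), resno = 1, elety = c("P1", "P2"))
    m <- toy_model(atoms, list(rbind(c(0, 0, 0), c(d, 0, 0))))
    pair <- atom_group_pair("t", data.frame(chain = "A", resno = 1, elety = "P1"),
                            data.frame(chain = "B", resno = 1, elety = "P2"),
                            kind = kind)
    detect_interaction(m, pair)
  }
  expect_true(mk(3.4, "hbond")$stable)
  expect_false(mk(3.6, "hbond")$stable)
  # a 4.2 A charged-group separation is not a salt bridge
  expect_false(mk(4.2, "saltbridge")$stable)
  expect_true(mk(4.0, "saltbridge")$stable)
})

test_that("ensemble occupancy recovers the prescribed contact probability", {
  tc <- fixture_template()
  pair <- fixture_saltbridge_pair()
  s <- sample_ensemble(synthetic_ensemble_spec(
    tc, 1000, seed = 21, contacts = list(contact_spec(pair, 0.7))))
  rec <- detect_interaction(s$model, pair)
  expect_equal(rec$occupancy, mean(s$truth$contact_states[, 1]))
  expect_lt(abs(rec$occupancy - 0.7), 0.05)
  expect_true(rec$stable)
})

test_that("occupancy is monotone in the distance cutoff", {
  tc <- fixture_template()
  pair <- fixture_saltbridge_pair()
  ens <- sample_ensemble(synthetic_ensemble_spec(
    tc, 300, seed = 33, contacts = list(contact_spec(pair, 0.5)),
    noise_sigma = 0.4))$model
  occ <- vapply(seq(3.0, 8.0, by = 0.5), function(cut)
    detect_interaction(ens, pair,
                       interaction_criteria(hbond_max_dist = cut,
                                            saltbridge_max_dist = cut))$occupancy,
    1)
  expect_true(all(diff(occ) >= 0))
})

test_that("candidate enumeration finds engineered contacts and nothing else", {
  tc <- fixture_template()
  pep <- assign_peptide_numbering(tc)
  dom <- build_sh2_annotation(tc)
  # template: peptide and scaffold are 15 A apart -> no backbone candidates
  expect_length(enumerate_candidate_pairs(tc, pep, dom, "backbone"), 0L)
  # engineer one backbone H-bond (+2 O to K91 N) and re-enumerate
  bb <- fixture_backbone_pair()
  bound <- sample_ensemble(synthetic_ensemble_spec(
    tc, 1, seed = 2, contacts = list(contact_spec(bb, 1.0)),
    noise_sigma = 0))$model
  found <- enumerate_candidate_pairs(bound, pep, dom, "backbone")
  expect_gte(length(found), 1L)
  labs <- vapply(found, function(p) p$label, "")
  expect_true(any(grepl("\\+2 O : K91 \\(BG7\\) N", labs)))
  # every found candidate is actually within the prefilter in that frame
  for (p in found)
    expect_lt(min_group_distance(frame_coords(bound), p, bound), 6.0)
})

test_that("the pY-pocket catalog lists the canonical probes", {
  tc <- fixture_template()
  pep <- assign_peptide_numbering(tc)
  dom <- build_sh2_annotation(tc)
  pp <- enumerate_candidate_pairs(tc, pep, dom, "pY_pocket")
  labs <- vapply(pp, function(p) p$label, "")
  kinds <- vapply(pp, function(p) p$kind, "")
  expect_length(pp, 7L)
  expect_true(any(grepl("S34", labs) & kinds == "hbond"))
  expect_true(any(grepl("K35 \\(BC1\\) N$", labs)))
  expect_true(any(grepl("S36", labs)))
  expect_true(any(grepl("T42.*OG1", labs)))
  expect_true(any(grepl("R32.*guanidinium", labs) & kinds == "saltbridge"))
  expect_equal(sum(grepl("NZ", labs) & kinds == "saltbridge"), 2L)  # K35, K55
  # all phosphate groups are the three terminal oxygens
  for (p in pp) expect_setequal(p$group_a$elety, c("O1P", "O2P", "O3P"))
})

test_that("sidechain catalog pairs charged groups as salt bridges", {
  tc <- fixture_template()   # +2 and +4 are Asp
  pep <- assign_peptide_numbering(tc)
  dom <- build_sh2_annotation(tc)
  sb <- fixture_saltbridge_pair()
  bound <- sample_ensemble(synthetic_ensemble_spec(
    tc, 1, seed = 4, contacts = list(contact_spec(sb, 1.0)),
    noise_sigma = 0))$model
  found <- enumerate_candidate_pairs(bound, pep, dom, "sidechain")
  kinds <- vapply(found, function(p) p$kind, "")
  labs <- vapply(found, function(p) p$label, "")
  expect_true(any(kinds == "saltbridge" & grepl("\\+2 D : K91", labs)))
})

test_that("distance distributions integrate to one and locate the mass", {
  tc <- fixture_template()
  rec <- structure(list(pair = fixture_saltbridge_pair(),
                        distance_series = rep(3.0, 100), occupancy = 1,
                        stable = TRUE, n_evaluable_frames = 100,
                        single_frame = FALSE),
                   class = "interaction_record")
  h <- distance_distribution(rec, 0.2)
  expect_equal(sum(h$density * (h$bin_right - h$bin_left)), 1)
  expect_equal(nrow(h[h$density > 0, ]), 1L)
  expect_true(h$bin_left[h$density > 0] <= 3.0 &&
                h$bin_right[h$density > 0] >= 3.0)
  # two-state series: equal mass at the two distances
  rec$distance_series <- rep(c(3.0, 8.0), 50)
  h2 <- distance_distribution(rec, 0.2)
  occupied <- h2[h2$density > 0, ]
  expect_equal(nrow(occupied), 2L)
  expect_equal(occupied$density * 0.2, c(0.5, 0.5))
  # Gaussian-noised series recovers its mean
  set.seed(77)
  rec$distance_series <- stats::rnorm(1e4, 3.5, 0.2)
  h3 <- distance_distribution(rec, 0.1)
  mids <- (h3$bin_left + h3$bin_right) / 2
  expect_lt(abs(sum(mids * h3$density * 0.1) - 3.5), 0.02)
  expect_equal(attr(h3, "reference"), 4.0)
  expect_error(distance_distribution(rec, 0), "positive")
})

test_that("table cells follow the print conventions", {
  mk_rec <- function(series, kind = "hbond", single = FALSE) {
    pair <- atom_group_pair(paste0("pair-", kind, "-", length(series), "-",
                                   signif(mean(series), 4)),
                            data.frame(chain = "A", resno = 1, elety = "X"),
                            data.frame(chain = "B", resno = 1, elety = "Y"),
                            kind = kind)
    cutoff <- if (kind == "hbond") 3.5 else 4.0
    occ <- mean(series <= cutoff, na.rm = TRUE)
    structure(list(pair = pair, distance_series = series,
                   occupancy = if (all(is.na(series))) NA else occ,
                   stable = if (single) isTRUE(series[1] <= cutoff)
                            else isTRUE(occ >= 0.5),
                   n_evaluable_frames = sum(!is.na(series)),
                   single_frame = single),
                 class = "interaction_record")
  }
  # ensemble at 73% persistence: integer percent cell, stable
  r73 <- mk_rec(c(rep(1, 73), rep(9, 27)))
  # ensemble at 4%: below the 5% reporting threshold -> dash
  r04 <- mk_rec(c(rep(1, 4), rep(9, 96)))
  tab <- build_interaction_table(list(r73, r04))
  expect_equal(tab[[r73$pair$label]], "73")
  expect_true(attr(tab, "stable")[1, r73$pair$label])
  expect_equal(tab[[r04$pair$label]], "-")
  # single frame at 2.8 A: one-decimal distance, stable
  s28 <- mk_rec(2.8, single = TRUE)
  s42 <- mk_rec(4.2, kind = "saltbridge", single = TRUE)
  s36 <- mk_rec(3.6, single = TRUE)
  sna <- mk_rec(NA_real_, single = TRUE)
  tab2 <- build_interaction_table(list(s28, s42, s36, sna))
  expect_equal(tab2[[s28$pair$label]], "2.8")
  expect_true(attr(tab2, "stable")[1, s28$pair$label])
  # salt-bridge distances print even beyond the cutoff, unbolded
  expect_equal(tab2[[s42$pair$label]], "4.2")
  expect_false(attr(tab2, "stable")[1, s42$pair$label])
  # an H-bond beyond the cutoff is "not formed" in a crystal structure
  expect_equal(tab2[[s36$pair$label]], "-")
  expect_equal(tab2[[sna$pair$label]], "n.a.")
})
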