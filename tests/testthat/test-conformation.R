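test_that("order parameter hits its analytic limits", {
  # fixed dihedral in every frame -> exactly 1
  expect_equal(chi1_order_parameter(rep(-60, 1000))$theta, 1)
  # antipodal two-state series -> exactly 0
  expect_equal(chi1_order_parameter(rep(c(-60, 120), 500))$theta, 0,
               tolerance = 1e-12)
  # theta always in [0, 1]
  set.seed(11)
  for (i in 1:20) {
    v <- stats::runif(sample(2:50, 1), -180, 180)
    th <- chi1_order_parameter(v)$theta
    expect_gte(th, 0); expect_lte(th, 1)
  }
})

test_that("order parameter is invariant under a global angle shift", {
  set.seed(12)
  v <- rvonmises(500, mu = 40, kappa = 1.5)
  base <- chi1_order_parameter(v)$theta
  for (shift in c(-170, -45, 30, 90, 180)) {
    shifted <- ((v + shift + 180) %% 360) - 180
    expect_equal(chi1_order_parameter(shifted)$theta, base, tolerance = 1e-9)
  }
})

test_that("order parameter recovers the von Mises Bessel ratio", {
  # oracle: the mean resultant length of a von Mises(kappa) is I1(k)/I0(k)
  set.seed(13)
  for (kappa in c(0.5, 1, 2, 4, 8)) {
    v <- rvonmises(1e4, mu = -60, kappa = kappa)
    th <- v * pi / 180
    est <- chi1_order_parameter(v)$theta
    rho <- besselI(kappa, 1) / besselI(kappa, 0)
    # empirical standard error of the resultant modulus (delta method)
    cbar <- mean(cos(th)); sbar <- mean(sin(th)); n <- length(v)
    vc <- stats::var(cos(th)) / n; vs <- stats::var(sin(th)) / n
    cv <- stats::cov(cos(th), sin(th)) / n
    se <- sqrt((cbar^2 * vc + sbar^2 * vs + 2 * cbar * sbar * cv)) /
      sqrt(cbar^2 + sbar^2)
    expect_lt(abs(est - rho), 3 * se + 1e-12)
  }
})

test_that("chi1 series are undefined for glycine and alanine", {
  tc <- fixture_template(peptide = "GAyL")
  prof <- chi1_profile(tc, "B")
  expect_false(prof$defined[prof$resid == "GLY"])
  expect_false(prof$defined[prof$resid == "ALA"])
  expect_true(prof$defined[prof$resid == "PTR"])
  expect_true(prof$defined[prof$resid == "LEU"])
  expect_error(chi1_order_parameter(
    structure(list(angle_name = "phi", values = 1:3, defined = TRUE),
              class = "dihedral_series")), "chi1")
})

test_that("chi1 extraction agrees with the bio3d torsion oracle", {
  tc <- fixture_template()
  ens <- sample_ensemble(synthetic_ensemble_spec(
    tc, 5, seed = 3,
    dihedrals = list(list(residue = residue_ref("B", 4, "ILE"),
                          dist = list(type = "vonmises", mu = -60, kappa = 3))),
    noise_sigma = 0.05))$model
  ours <- chi1_series(ens, residue_ref("B", 4, "ILE"))$values
  idx <- vapply(c("N", "CA", "CB", "CG1"), function(at)
    atom_indices(ens, chain = "B", resno = 4, elety = at)[1], 1L)
  oracle <- vapply(seq_len(5), function(f) {
    x <- frame_coords(ens, f)
    bio3d::torsion.xyz(as.vector(t(x[idx, ])), atm.inc = 4)
  }, 1)
  expect_equal(ours, unname(oracle), tolerance = 1e-6)
})

test_that("RMSF matches closed forms", {
  # identical frames -> zero everywhere
  tc <- fixture_template(peptide = "AyA", domain_residues = .MINI_DOMAIN[1:6])
  ens0 <- sample_ensemble(synthetic_ensemble_spec(tc, 10, seed = 1,
                                                  noise_sigma = 0))$model
  expect_true(all(residue_rmsf(ens0)$rmsf < 1e-9))
  # isotropic Gaussian jitter on the target, rigid fit subset:
  # per-atom RMSF -> sigma * sqrt(3)
  set.seed(19)
  n_fit <- 10; n_tgt <- 4; nf <- 5000; sigma <- 0.5
  base <- matrix(stats::runif((n_fit + n_tgt) * 3, -10, 10), ncol = 3)
  atoms <- data.frame(chain = rep(c("A", "B"), c(n_fit, n_tgt)),
                      resno = c(rep(1, n_fit), seq_len(n_tgt)),
                      elety = c(paste0("C", 1:n_fit), rep("CA", n_tgt)))
  frames <- lapply(seq_len(nf), function(i) {
    f <- base
    f[n_fit + (1:n_tgt), ] <- f[n_fit + (1:n_tgt), ] +
      matrix(stats::rnorm(n_tgt * 3, 0, sigma), ncol = 3)
    f
  })
  m <- toy_model(atoms, frames)
  prof <- residue_rmsf(m, fit_selection = 1:n_fit, target = "B")
  expect_equal(mean(prof$rmsf), sigma * sqrt(3), tolerance = 0.02)
  # two-state atom hopping d = 2.4 A -> RMSF = d/2 = 1.2
  frames2 <- lapply(seq_len(100), function(i) {
    f <- base
    f[n_fit + 1, 1] <- f[n_fit + 1, 1] + if (i %% 2 == 0) 1.2 else -1.2
    f
  })
  m2 <- toy_model(atoms, frames2)
  prof2 <- residue_rmsf(m2, fit_selection = 1:n_fit, target = "B")
  expect_equal(prof2$rmsf[1], 1.2, tolerance = 1e-6)
  expect_true(all(prof2$rmsf[-1] < 1e-6))
  # low-mobility flag: within 1 A of the profile minimum
  expect_true(prof2$low_mobility[2])
  expect_false(prof2$low_mobility[1])
  expect_error(residue_rmsf(subset_frames(m, 1)), "2 frames")
})

test_that("RMSF is invariant under global rigid-body motion", {
  tc <- fixture_template(peptide = "LNyID")
  ens <- sample_ensemble(synthetic_ensemble_spec(tc, 40, seed = 8,
                                                 noise_sigma = 0.2))$model
  prof <- residue_rmsf(ens)
  # rotate + translate every frame by a frame-dependent rigid motion
  moved <- ens
  set.seed(9)
  for (f in seq_len(n_frames(ens))) {
    x <- matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE)
    th <- stats::runif(1, 0, 360)
    x <- sh2pep:::.rotate_about_axis(x, origin = c(0, 0, 0),
                                     axis = c(1, 1, 1), theta = th)
    x <- sweep(x, 2, stats::runif(3, -20, 20), `+`)
    moved$xyz[f, ] <- as.vector(t(x))
  }
  prof2 <- residue_rmsf(moved)
  expect_equal(prof2$rmsf, prof$rmsf, tolerance = 1e-6)
})

test_that("phi/psi values and regions are computed correctly", {
  # builder backbone is extended: top-left (beta) region
  tc <- fixture_template(peptide = "LNyID")
  bd <- backbone_dihedrals(tc, list(residue_ref("B", 3, "")))
  expect_equal(bd$phi, -120, tolerance = 1e-6)
  expect_equal(bd$psi, 130, tolerance = 1e-6)
  expect_equal(bd$region, "beta_extended")
  # canonical helical point
  expect_equal(classify_rama(-63, -43), "alpha_R")
  expect_equal(classify_rama(-120, 130), "beta_extended")
  expect_equal(classify_rama(60, 45), "alpha_L")
  expect_equal(classify_rama(0, -180), "other")
  # planar zigzag tetrapeptide: hand-constructed phi of 180 degrees
  atoms <- data.frame(chain = rep(c("A", "B", "B", "B"), c(1, 1, 1, 1)),
                      resno = c(1, 1, 2, 3),
                      elety = c("CA", "C", "N", "N"))
  # hand model: use a 3-residue peptide chain B with residue 2 complete
  atoms <- data.frame(
    chain = c("A", rep("B", 8)),
    resno = c(1, 1, 1, 1, 2, 2, 2, 3, 3),
    elety = c("CA", "N", "CA", "C", "N", "CA", "C", "N", "CA"))
  zig <- rbind(c(99, 99, 99),                     # far-away domain atom
               c(0, 1, 0), c(1, 0, 0), c(2, 1, 0),  # res 1 backbone
               c(3, 0, 0), c(4, 1, 0), c(5, 0, 0),  # res 2 backbone
               c(6, 1, 0), c(7, 0, 0))              # res 3
  m <- toy_model(atoms, list(zig))
  bd2 <- backbone_dihedrals(m, list(residue_ref("B", 2, "")))
  expect_equal(abs(bd2$phi), 180, tolerance = 1e-9)
  expect_equal(abs(bd2$psi), 180, tolerance = 1e-9)
  # residues without flanking neighbors are skipped with a message
  expect_message(out <- backbone_dihedrals(m, list(residue_ref("B", 1, ""))),
                 "flanking")
  expect_equal(nrow(out), 0L)
})

test_that("loop metrics reproduce engineered geometry", {
  # BC residues each exactly 5 A from the pocket probe; EF/BG sharing a
  # coincident atom; a sheet probe pair at a hand-computed distance
  bc_res <- 34:38
  atoms <- data.frame(
    chain = c(rep("A", length(bc_res)), "A", "A", "A", "A", "A", "B"),
    resno = c(bc_res, 42, 66, 84, 40, 57, 1),
    elety = c(rep("CA", length(bc_res)), "CA", "CA", "CA", "C", "N", "CA"))
  coords <- rbind(
    t(vapply(seq_along(bc_res), function(i) {
      ang <- 2 * pi * i / 8
      5 * c(cos(ang), sin(ang), 0)
    }, numeric(3))),
    c(0, 0, 0),          # probe residue 42 at the center
    c(30, 0, 0),         # EF residue 66
    c(30, 0, 0),         # BG residue 84 - coincident with EF
    c(0, 10, 0),         # sheet probe a: res 40 atom C
    c(3, 14, 0),         # sheet probe b: res 57 atom N
    c(60, 60, 60))       # token peptide atom
  m <- toy_model(atoms, list(coords))
  dom <- structure(list(map = c("βC1" = 40L, "βD′1" = 57L, "βC3" = 42L),
                        chain = "A", loop_bc = bc_res, loop_ef = 66L,
                        loop_bg = 84L,
                        sheet_probe = list(a = list(resno = 40, elety = "C"),
                                           b = list(resno = 57, elety = "N")),
                        pocket_probe = 42L),
                   class = "sh2_annotation")
  lm <- loop_metrics(m, dom)
  expect_equal(lm$bc_t42_avg, 5.0, tolerance = 1e-9)
  expect_equal(lm$ef_bg_min, 0.0)
  expect_equal(lm$sheet_cd, 5.0, tolerance = 1e-9)  # sqrt(3^2 + 4^2)
  # independent coordinate-arithmetic oracle on the synthetic template
  tc <- fixture_template()
  dom2 <- build_sh2_annotation(tc)
  lm2 <- loop_metrics(tc, dom2)
  x <- frame_coords(tc)
  ia <- atom_indices(tc, chain = "A", resno = 40, elety = "C")
  ib <- atom_indices(tc, chain = "A", resno = 57, elety = "N")
  expect_equal(lm2$sheet_cd, sqrt(sum((x[ia, ] - x[ib, ])^2)),
               tolerance = 1e-9)
})

test_that("representative structure is the centroid of the biggest cluster", {
  tc <- fixture_template(peptide = "AyA", domain_residues = .MINI_DOMAIN[1:6])
  # identical frames: lowest index wins
  ens0 <- sample_ensemble(synthetic_ensemble_spec(tc, 8, seed = 1,
                                                  noise_sigma = 0))$model
  expect_equal(representative_structure(ens0), 1L)
  # 99 near-identical frames + 1 far outlier: never the outlier
  ens1 <- sample_ensemble(synthetic_ensemble_spec(tc, 99, seed = 2,
                                                  noise_sigma = 0.05))$model
  out_frame <- ens1$xyz[1, ] + rep(c(10, 0, 0), n_atoms(ens1))
  ens1$xyz <- rbind(ens1$xyz, out_frame)
  expect_lt(representative_structure(ens1), 100L)
  # 70/30 bimodal ensemble: representative comes from the majority mode
  set.seed(31)
  shift <- rep(c(8, 0, 0), n_atoms(tc))
  xyzA <- matrix(rep(tc$xyz[1, ], 70), nrow = 70, byrow = TRUE) +
    matrix(stats::rnorm(70 * length(tc$xyz[1, ]), 0, 0.1), nrow = 70)
  xyzB <- matrix(rep(tc$xyz[1, ] + shift, 30), nrow = 30, byrow = TRUE) +
    matrix(stats::rnorm(30 * length(tc$xyz[1, ]), 0, 0.1), nrow = 30)
  bim <- tc
  bim$xyz <- rbind(xyzA, xyzB)
  expect_lte(representative_structure(bim), 70L)
})

test_that("greedy clustering agrees with exhaustive search on small ensembles", {
  tc <- fixture_template(peptide = "Ly", domain_residues = .MINI_DOMAIN[1:4])
  sel <- atom_indices(tc, elety = c("N", "CA", "C"))
  for (seed in 1:5) {
    nf <- c(10, 20, 30, 40, 50)[seed]
    ens <- sample_ensemble(synthetic_ensemble_spec(tc, nf, seed = seed,
                                                   noise_sigma = 0.45))$model
    got <- representative_structure(ens, selection = sel, cutoff = 1.0)
    # independent oracle: explicit pairwise matrix + greedy peeling by hand
    rms <- matrix(0, nf, nf)
    sub <- ens$xyz[, sh2pep:::.xyz_cols(sel), drop = FALSE]
    for (i in 1:nf) for (j in 1:nf) if (i != j)
      rms[i, j] <- bio3d::rmsd(sub[i, ], sub[j, ], fit = TRUE)
    nb <- rms <= 1.0
    remaining <- rep(TRUE, nf); best <- NA; best_n <- -1
    while (any(remaining)) {
      cnt <- vapply(1:nf, function(i)
        if (remaining[i]) sum(nb[i, ] & remaining) else -1L, 1L)
      ctr <- which.max(cnt)
      mem <- which(nb[ctr, ] & remaining)
      if (length(mem) > best_n) { best_n <- length(mem); best <- ctr }
      remaining[mem] <- FALSE
    }
    expect_equal(got, best)
  }
})

test_that("block averaging flags convergence correctly", {
  # constant series: SEM identically zero, converged
  rep0 <- block_average(rep(2.5, 512))
  expect_true(all(rep0$sem == 0))
  expect_true(attr(rep0, "converged"))
  # white noise: SEM ~ 1/sqrt(N) at every block count, within 4 standard
  # deviations of the SEM estimator (relative sd ~ 1/sqrt(2(nb-1)))
  set.seed(55)
  n <- 1e4
  w <- stats::rnorm(n)
  repw <- block_average(w)
  tol <- 4 / sqrt(2 * (repw$n_blocks - 1))
  expect_true(all(abs(repw$sem - 1 / sqrt(n)) / (1 / sqrt(n)) < tol))
  # with enough blocks the SEM estimator is tight and the plateau flag is
  # reliable for uncorrelated data
  repw2 <- block_average(stats::rnorm(2^15),
                         n_blocks_list = c(512, 256))
  expect_true(attr(repw2, "converged"))
  # linear ramp: SEM inflates with block size; closed-form oracle at each
  # block count (block means of a ramp are equally spaced)
  ramp <- seq(0, 1, length.out = 2^13)
  repr <- block_average(ramp)
  oracle <- vapply(repr$n_blocks, function(nb) {
    bs <- floor(length(ramp) / nb)
    bm <- colMeans(matrix(ramp[1:(nb * bs)], nrow = bs))
    stats::sd(bm) / sqrt(nb)
  }, 1)
  expect_equal(repr$sem, oracle, tolerance = 1e-12)
  expect_true(all(diff(repr$sem) > 0))   # grows as blocks get larger
  expect_false(attr(repr, "converged"))
  expect_error(block_average(rnorm(10), n_blocks_list = c(16, 8)), "too short")
})
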