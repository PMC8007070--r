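# gamma heavy atom defining chi1 (N-CA-CB-gamma), by residue type
.CHI1_GAMMA <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG", GLU = "CG",
  HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
  PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1",
  PTR = "CG")

#' Per-frame chi1 dihedral series
#'
#' Computes the chi1 side-chain dihedral (N-CA-CB-gamma heavy atom, with the
#' standard gamma-atom choice per residue type; phosphotyrosine follows the
#' tyrosine definition) for every frame. Glycine and alanine have no chi1 and
#' yield a series marked undefined.
#'
#' @param model a `complex_model`
#' @param residue a [residue_ref()]
#' @return a `dihedral_series`: list with `residue`, `angle_name`, `values`
#'   (degrees in (-180, 180], length `n_frames`), `defined`
#' @export
chi1_series <- function(model, residue) {
  resid <- residue$resid
  if (!nzchar(resid)) {
    i <- atom_indices(model, chain = residue$chain, resno = residue$resno,
                      insert = residue$insert)[1L]
    resid <- model$atoms$resid[i]
  }
  gamma <- if (resid %in% names(.CHI1_GAMMA)) .CHI1_GAMMA[[resid]] else NULL
  if (resid %in% c("GLY", "ALA") || is.null(gamma)) {
    return(structure(list(residue = residue, angle_name = "chi1",
                          values = rep(NA_real_, n_frames(model)),
                          defined = FALSE),
                     class = "dihedral_series"))
  }
  idx <- vapply(c("N", "CA", "CB", gamma), function(at) {
    j <- atom_indices(model, chain = residue$chain, resno = residue$resno,
                      elety = at, insert = residue$insert)
    if (length(j) == 0L) NA_integer_ else j[1L]
  }, 1L)
  if (anyNA(idx)) {
    return(structure(list(residue = residue, angle_name = "chi1",
                          values = rep(NA_real_, n_frames(model)),
                          defined = FALSE),
                     class = "dihedral_series"))
  }
  p <- lapply(idx, function(i)
    model$xyz[, .xyz_cols(i), drop = FALSE])
  vals <- .dihedral(p[[1L]], p[[2L]], p[[3L]], p[[4L]])
  structure(list(residue = residue, angle_name = "chi1", values = vals,
                 defined = TRUE),
            class = "dihedral_series")
}

#' Circular order parameter of a chi1 series
#'
#' The order parameter is the modulus of the circular mean of the per-frame
#' unit vectors at the dihedral angle:
#' theta = | (1/N) * sum_i (cos chi_i, sin chi_i) |.
#' It equals 1 for a dihedral fixed across all frames and tends to 0 for free
#' rotation, and is invariant under a global additive shift of all angles.
#' It is undefined for glycine and alanine (no chi1).
#'
#' @param series a `dihedral_series` with `angle_name == "chi1"`, or a bare
#'   numeric vector of angles in degrees
#' @return an `order_parameter_result`: list with `residue`, `theta`,
#'   `n_frames`, `defined`
#' @export
chi1_order_parameter <- function(series) {
  if (is.numeric(series))
    series <- structure(list(residue = NULL, angle_name = "chi1",
                             values = series, defined = TRUE),
                        class = "dihedral_series")
  if (!identical(series$angle_name, "chi1"))
    stop("order parameter is defined here for chi1 series only", call. = FALSE)
  if (!series$defined) {
    return(structure(list(residue = series$residue, theta = NA_real_,
                          n_frames = length(series$values), defined = FALSE),
                     class = "order_parameter_result"))
  }
  v <- series$values[!is.na(series$values)]
  if (length(v) == 0L) stop("no frames in dihedral series", call. = FALSE)
  th <- .deg2rad(v)
  theta <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  structure(list(residue = series$residue, theta = theta,
                 n_frames = length(v), defined = TRUE),
            class = "order_parameter_result")
}

#' Chi1 order-parameter profile of a chain
#'
#' @param model a `complex_model`
#' @param chain chain identifier
#' @return data frame with one row per residue: `resno`, `resid`, `theta`,
#'   `defined` (`theta` is `NA` and `defined` `FALSE` for Gly/Ala)
#' @export
chi1_profile <- function(model, chain) {
  a <- model$atoms
  res <- unique(a[a$chain == chain, c("chain", "resno", "insert", "resid")])
  out <- lapply(seq_len(nrow(res)), function(i) {
    r <- residue_ref(res$chain[i], res$resno[i], res$resid[i], res$insert[i])
    op <- chi1_order_parameter(chi1_series(model, r))
    data.frame(resno = r$resno, resid = r$resid, theta = op$theta,
               defined = op$defined, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-residue RMSF after least-squares superposition
#'
#' Frames are superposed on `fit_selection` (atom row indices; by default the
#' domain backbone N/CA/C), removing global rigid-body motion; the per-atom
#' RMSF is the root-mean-square deviation from the atom's mean position, and
#' the per-residue value averages the residue's aggregation atoms (all heavy
#' atoms, or backbone N/CA/C/O). Residues whose RMSF is within 1 Angstrom of
#' the profile minimum are flagged low-mobility.
#'
#' @param model a `complex_model` with at least 2 frames
#' @param fit_selection integer atom row indices used for superposition
#' @param target chain whose residues are profiled
#' @param aggregation `"all_heavy"` or `"backbone_atoms"`
#' @return an `rmsf_profile` data frame: `resno`, `resid`, `rmsf`, `low_mobility`
#' @export
residue_rmsf <- function(model,
                         fit_selection = atom_indices(
                           model, chain = model$domain_chain,
                           elety = c("N", "CA", "C")),
                         target = model$peptide_chain,
                         aggregation = c("all_heavy", "backbone_atoms")) {
  aggregation <- match.arg(aggregation)
  if (n_frames(model) < 2L)
    stop("RMSF needs at least 2 frames", call. = FALSE)
  fit_cols <- .xyz_cols(fit_selection)
  xyz <- bio3d::fit.xyz(fixed = model$xyz[1L, ], mobile = model$xyz,
                        fixed.inds = fit_cols, mobile.inds = fit_cols)
  a <- model$atoms
  res <- unique(a[a$chain == target, c("chain", "resno", "insert", "resid")])
  per_res <- vapply(seq_len(nrow(res)), function(i) {
    idx <- atom_indices(model, chain = res$chain[i], resno = res$resno[i],
                        insert = res$insert[i])
    idx <- idx[a$elesy[idx] != "H"]
    if (aggregation == "backbone_atoms")
      idx <- idx[a$elety[idx] %in% c("N", "CA", "C", "O")]
    if (length(idx) == 0L) return(NA_real_)
    atom_rmsf <- vapply(idx, function(j) {
      x <- xyz[, .xyz_cols(j), drop = FALSE]
      mu <- colMeans(x)
      sqrt(mean(rowSums(sweep(x, 2, mu)^2)))
    }, 1)
    mean(atom_rmsf)
  }, 1)
  out <- data.frame(resno = res$resno, resid = res$resid, rmsf = per_res,
                    stringsAsFactors = FALSE)
  out$low_mobility <- out$rmsf < min(out$rmsf, na.rm = TRUE) + 1.0
  structure(out, class = c("rmsf_profile", "data.frame"),
            fit_selection = fit_selection, aggregation = aggregation)
}

#' Backbone phi/psi dihedrals with region classification
#'
#' Computes phi (C[i-1]-N-CA-C) and psi (N-CA-C-N[i+1]) for each requested
#' residue in every frame and classifies the conformation into Ramachandran
#' regions (beta_extended / alpha_R / alpha_L / other) using the configured
#' region polygons for the residue class (generic, Gly, Pro). Residues whose
#' flanking atoms are missing are skipped with a message.
#'
#' @param model a `complex_model`
#' @param residues list of [residue_ref()]
#' @param regions region polygons, as from [rama_regions()]
#' @return data frame: `resno`, `resid`, `frame`, `phi`, `psi`, `region`
#' @export
backbone_dihedrals <- function(model, residues, regions = rama_regions()) {
  a <- model$atoms
  chain_res <- function(ch) {
    r <- unique(a[a$chain == ch, c("chain", "resno", "insert", "resid")])
    rownames(r) <- NULL
    r
  }
  out <- list()
  for (rr in residues) {
    res <- chain_res(rr$chain)
    pos <- which(res$resno == rr$resno & res$insert == rr$insert)
    if (length(pos) != 1L || pos == 1L || pos == nrow(res)) {
      message(sprintf("skipping %s %d: no flanking residues", rr$chain, rr$resno))
      next
    }
    get <- function(p, at) {
      j <- atom_indices(model, chain = res$chain[p], resno = res$resno[p],
                        elety = at, insert = res$insert[p])
      if (length(j) == 0L) NA_integer_ else j[1L]
    }
    idx <- c(get(pos - 1L, "C"), get(pos, "N"), get(pos, "CA"),
             get(pos, "C"), get(pos + 1L, "N"))
    if (anyNA(idx)) {
      message(sprintf("skipping %s %d: missing backbone atoms", rr$chain, rr$resno))
      next
    }
    p <- lapply(idx, function(i) model$xyz[, .xyz_cols(i), drop = FALSE])
    phi <- .dihedral(p[[1L]], p[[2L]], p[[3L]], p[[4L]])
    psi <- .dihedral(p[[2L]], p[[3L]], p[[4L]], p[[5L]])
    resid <- res$resid[pos]
    cls <- if (resid == "GLY") "gly" else if (resid == "PRO") "pro" else "generic"
    out[[length(out) + 1L]] <- data.frame(
      resno = rr$resno, resid = resid, frame = seq_len(n_frames(model)),
      phi = phi, psi = psi,
      region = classify_rama(phi, psi, cls, regions),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(resno = integer(), resid = character(),
                      frame = integer(), phi = numeric(), psi = numeric(),
                      region = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Loop and sheet conformational metrics
#'
#' Three per-frame series characterizing the mobile regions of the domain:
#' * `bc_t42_avg` - mean over the BC-loop residues of the minimum heavy-atom
#'   distance from each residue to the pocket probe residue (T42-equivalent);
#'   a closed pY pocket gives small values;
#' * `ef_bg_min` - minimum heavy-atom distance between the EF and BG loops,
#'   which gate the specificity groove;
#' * `sheet_cd` - the central-sheet interstrand distance between the C atom
#'   of the βC1 residue and the N atom of the βD'1 residue.
#'
#' The BC-residue distance uses nearest heavy atoms by default
#' (`bc_mode = "min_heavy"`), which is robust to side-chain composition;
#' `"ca"` switches to Cα-Cα.
#'
#' @param model a `complex_model`
#' @param dom an `sh2_annotation`
#' @param bc_mode `"min_heavy"` or `"ca"`
#' @return a `loop_metric_series`: list of three numeric per-frame series
#'   (`NA`-filled when a probe atom is missing, for that series only) plus a
#'   `summary` data frame (mean, sd per series)
#' @export
loop_metrics <- function(model, dom, bc_mode = c("min_heavy", "ca")) {
  bc_mode <- match.arg(bc_mode)
  a <- model$atoms
  nf <- n_frames(model)
  heavy <- function(resno) {
    idx <- atom_indices(model, chain = dom$chain, resno = resno)
    idx[a$elesy[idx] != "H"]
  }
  series_min <- function(ia, ib) {
    if (length(ia) == 0L || length(ib) == 0L) return(rep(NA_real_, nf))
    best <- rep(Inf, nf)
    for (i in ia) {
      xi <- model$xyz[, .xyz_cols(i), drop = FALSE]
      for (j in ib) {
        best <- pmin(best, rowSums((xi - model$xyz[, .xyz_cols(j), drop = FALSE])^2))
      }
    }
    sqrt(best)
  }
  # BC loop vs pocket probe
  probe_idx <- if (bc_mode == "ca")
    atom_indices(model, chain = dom$chain, resno = dom$pocket_probe, elety = "CA")
  else heavy(dom$pocket_probe)
  bc_per_res <- lapply(dom$loop_bc, function(rn) {
    ia <- if (bc_mode == "ca")
      atom_indices(model, chain = dom$chain, resno = rn, elety = "CA")
    else heavy(rn)
    series_min(ia, probe_idx)
  })
  bc_t42_avg <- if (length(bc_per_res) == 0L) rep(NA_real_, nf)
    else rowMeans(do.call(cbind, bc_per_res))
  # EF vs BG minimum
  ef_idx <- unlist(lapply(dom$loop_ef, heavy))
  bg_idx <- unlist(lapply(dom$loop_bg, heavy))
  ef_bg_min <- series_min(ef_idx, bg_idx)
  # central sheet probe pair
  ia <- atom_indices(model, chain = dom$chain, resno = dom$sheet_probe$a$resno,
                     elety = dom$sheet_probe$a$elety)
  ib <- atom_indices(model, chain = dom$chain, resno = dom$sheet_probe$b$resno,
                     elety = dom$sheet_probe$b$elety)
  sheet_cd <- series_min(ia, ib)
  summ <- data.frame(
    metric = c("bc_t42_avg", "ef_bg_min", "sheet_cd"),
    mean = c(mean(bc_t42_avg), mean(ef_bg_min), mean(sheet_cd)),
    sd = c(stats::sd(bc_t42_avg), stats::sd(ef_bg_min), stats::sd(sheet_cd)),
    stringsAsFactors = FALSE)
  structure(list(bc_t42_avg = bc_t42_avg, ef_bg_min = ef_bg_min,
                 sheet_cd = sheet_cd, summary = summ),
            class = "loop_metric_series")
}

#' Representative structure of an ensemble
#'
#' Greedy neighbor-count RMSD clustering: frames are pairwise superposed on
#' `selection`, each frame's neighbors are the frames within `cutoff` RMSD,
#' and clusters are peeled off greedily - the frame with the most remaining
#' neighbors (ties to the lowest frame number) becomes a cluster center and
#' its neighborhood is removed. The returned frame is the center of the
#' largest cluster; deterministic given frame order.
#'
#' @param model a `complex_model`
#' @param selection atom row indices used for RMSD (default: backbone N/CA/C
#'   of both chains)
#' @param cutoff RMSD cutoff in Angstrom
#' @return 1-based frame number of the representative frame
#' @export
representative_structure <- function(model,
                                     selection = atom_indices(
                                       model, elety = c("N", "CA", "C")),
                                     cutoff = 2.0) {
  nf <- n_frames(model)
  if (nf == 1L) return(1L)
  rms <- .pairwise_rmsd(model, selection)
  neighbor <- rms <= cutoff   # includes self
  remaining <- rep(TRUE, nf)
  best_center <- NA_integer_
  best_size <- -1L
  while (any(remaining)) {
    counts <- colSums(neighbor & remaining)
    counts[!remaining] <- -1L
    center <- which.max(counts)   # ties -> lowest index
    members <- which(neighbor[, center] & remaining)
    if (length(members) > best_size) {
      best_size <- length(members)
      best_center <- center
    }
    remaining[members] <- FALSE
  }
  as.integer(best_center)
}

#' @noRd
#' Full pairwise RMSD matrix over `selection`, with per-pair least-squares
#' superposition (Kabsch via the 3x3 cross-covariance SVD). Equivalent to
#' pairwise bio3d::rmsd(fit = TRUE) but avoids its per-call overhead, which
#' dominates on the O(frames^2) matrix.
.pairwise_rmsd <- function(model, selection) {
  cols <- .xyz_cols(selection)
  nf <- n_frames(model)
  k <- length(selection)
  centered <- vector("list", nf)
  gyr <- numeric(nf)
  for (f in seq_len(nf)) {
    x <- matrix(model$xyz[f, cols], ncol = 3L, byrow = TRUE)
    x <- sweep(x, 2, colMeans(x))
    centered[[f]] <- x
    gyr[f] <- sum(x * x)
  }
  rms <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    xi <- centered[[i]]
    for (j in (i + 1L):nf) {
      h <- crossprod(xi, centered[[j]])
      sv <- svd(h)
      d <- sv$d
      if (det(h) < 0) d[3L] <- -d[3L]
      msd <- max(0, (gyr[i] + gyr[j] - 2 * sum(d)) / k)
      rms[i, j] <- rms[j, i] <- sqrt(msd)
    }
  }
  rms
}

#' Block-averaging convergence report
#'
#' Splits the series into `n_blocks` equal blocks for each entry of
#' `n_blocks_list`, computes block means and the standard error of the series
#' mean as `sd(block means)/sqrt(n_blocks)`. For a converged (stationary,
#' decorrelated-at-block-size) series the SEM plateaus as blocks grow; the
#' `converged` flag requires the relative SEM change between the two largest
#' block sizes (the two smallest block counts) to be below `plateau_tol`
#' (20%).
#'
#' Block counts requiring blocks shorter than 2 frames are dropped; an error
#' is raised only when no requested count is feasible. The SEM estimated
#' from few blocks is itself noisy (relative sd about `1/sqrt(2(n_blocks-1))`),
#' so plateau detection is only as reliable as the smallest block counts in
#' the list; for long series prefer counts of a few tens or more.
#'
#' @param series numeric per-frame series
#' @param n_blocks_list block counts to evaluate (each at least 2)
#' @param plateau_tol relative SEM change tolerated at the plateau
#' @return a `block_average_report`: data frame (`n_blocks`, `block_size`,
#'   `sem`) with attributes `converged` and `block_means`
#' @export
block_average <- function(series, n_blocks_list = c(64L, 32L, 16L, 8L, 4L, 2L),
                          plateau_tol = 0.20) {
  n_blocks_list <- sort(unique(as.integer(n_blocks_list)), decreasing = TRUE)
  stopifnot(all(n_blocks_list >= 2L))
  n_blocks_list <- n_blocks_list[2L * n_blocks_list <= length(series)]
  if (length(n_blocks_list) < 2L)
    stop(sprintf("series too short (%d) for the requested block counts",
                 length(series)), call. = FALSE)
  means <- list()
  rows <- lapply(n_blocks_list, function(nb) {
    bs <- floor(length(series) / nb)
    use <- series[seq_len(nb * bs)]
    bm <- colMeans(matrix(use, nrow = bs))
    means[[as.character(nb)]] <<- bm
    data.frame(n_blocks = nb, block_size = bs,
               sem = stats::sd(bm) / sqrt(nb))
  })
  rep_df <- do.call(rbind, rows)
  k <- nrow(rep_df)
  s1 <- rep_df$sem[k - 1L]   # second-largest block size
  s2 <- rep_df$sem[k]        # largest block size
  converged <- if (max(s1, s2) == 0) TRUE else abs(s2 - s1) / max(s1, 1e-12) < plateau_tol
  structure(rep_df, class = c("block_average_report", "data.frame"),
            converged = converged, block_means = means)
}
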