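#' Interaction criteria
#'
#' Geometric criteria for interface contacts, heavy-atom throughout: hydrogen
#' bond if the donor-acceptor distance is at most `hbond_max_dist` (3.5
#' Angstrom), salt bridge if the minimum charged-group distance is at most
#' `saltbridge_max_dist` (4.0 Angstrom). On ensembles an interaction is
#' *stable* when its occupancy reaches `persistence_stable_min` (50%) and is
#' reported at all only above `report_min` (5%); on single structures stable
#' means the distance criterion holds. An optional donor-H-acceptor angle
#' filter (`hbond_min_angle`, degrees) can be enabled for inputs that carry
#' hydrogens; it is off by default so that structures without hydrogens are
#' treated identically.
#'
#' @param hbond_max_dist heavy-atom H-bond cutoff, Angstrom
#' @param saltbridge_max_dist charged-group salt-bridge cutoff, Angstrom
#' @param persistence_stable_min stable-occupancy threshold, fraction
#' @param report_min reporting threshold, fraction
#' @param hbond_min_angle optional donor-H-acceptor angle cutoff in degrees;
#'   `NULL` (default) disables the angle term
#' @return an `interaction_criteria`
#' @export
interaction_criteria <- function(hbond_max_dist = 3.5,
                                 saltbridge_max_dist = 4.0,
                                 persistence_stable_min = 0.50,
                                 report_min = 0.05,
                                 hbond_min_angle = NULL) {
  stopifnot(hbond_max_dist > 0, saltbridge_max_dist > 0,
            persistence_stable_min >= 0, persistence_stable_min <= 1,
            report_min >= 0, report_min <= 1)
  structure(list(hbond_max_dist = hbond_max_dist,
                 saltbridge_max_dist = saltbridge_max_dist,
                 persistence_stable_min = persistence_stable_min,
                 report_min = report_min,
                 hbond_min_angle = hbond_min_angle),
            class = "interaction_criteria")
}

#' Candidate interaction between two atom groups
#'
#' The two groups are sets of named atoms (e.g. the three phosphate oxygens
#' of the pY against an arginine guanidinium). The per-frame distance of the
#' pair is the minimum over all cross-group atom combinations, which is the
#' convention under which the 4.0 Angstrom salt-bridge rule reproduces
#' charged-group contact tables.
#'
#' @param label display label, e.g. `"+2 O : K91 N (BG7)"`
#' @param group_a,group_b data frames with columns `chain`, `resno`, `elety`
#'   (and optionally `insert`)
#' @param kind `"hbond"` or `"saltbridge"`
#' @return an `atom_group_pair`
#' @export
atom_group_pair <- function(label, group_a, group_b,
                            kind = c("hbond", "saltbridge")) {
  kind <- match.arg(kind)
  fix <- function(g) {
    stopifnot(is.data.frame(g), nrow(g) >= 1L,
              all(c("chain", "resno", "elety") %in% names(g)))
    if (is.null(g$insert)) g$insert <- ""
    g[, c("chain", "resno", "insert", "elety")]
  }
  group_a <- fix(group_a)
  group_b <- fix(group_b)
  ka <- do.call(paste, c(group_a, sep = "\r"))
  kb <- do.call(paste, c(group_b, sep = "\r"))
  if (length(intersect(ka, kb)) > 0L)
    stop("atom groups must be disjoint", call. = FALSE)
  structure(list(label = label, group_a = group_a, group_b = group_b,
                 kind = kind),
            class = "atom_group_pair")
}

# atom row indices for one group; NULL if any atom is missing
.group_indices <- function(model, group) {
  idx <- integer(nrow(group))
  for (i in seq_len(nrow(group))) {
    j <- atom_indices(model, chain = group$chain[i], resno = group$resno[i],
                      elety = group$elety[i], insert = group$insert[i])
    if (length(j) == 0L) return(NULL)
    idx[i] <- j[1L]
  }
  idx
}

#' Minimum cross-group distance in one frame
#'
#' @param frame an `n x 3` coordinate matrix (as from [frame_coords()])
#' @param pair an [atom_group_pair()]
#' @param model the `complex_model` the frame belongs to (for atom lookup)
#' @return distance in Angstrom, or `NA_real_` when any named atom is absent
#'   (propagated as not-evaluable, never silently zero)
#' @export
min_group_distance <- function(frame, pair, model) {
  ia <- .group_indices(model, pair$group_a)
  ib <- .group_indices(model, pair$group_b)
  if (is.null(ia) || is.null(ib)) return(NA_real_)
  .min_cross_dist(frame[ia, , drop = FALSE], frame[ib, , drop = FALSE])
}

#' @noRd
#' Per-frame minimum cross-group distances over a whole model, vectorized.
#' Returns numeric(n_frames), all NA if any atom is missing.
.group_distance_series <- function(model, pair) {
  nf <- n_frames(model)
  ia <- .group_indices(model, pair$group_a)
  ib <- .group_indices(model, pair$group_b)
  if (is.null(ia) || is.null(ib)) return(rep(NA_real_, nf))
  best <- rep(Inf, nf)
  for (i in ia) {
    xi <- model$xyz[, .xyz_cols(i), drop = FALSE]
    for (j in ib) {
      d2 <- rowSums((xi - model$xyz[, .xyz_cols(j), drop = FALSE])^2)
      best <- pmin(best, d2)
    }
  }
  sqrt(best)
}

#' Detect one interaction across all frames
#'
#' Computes the per-frame minimum cross-group distance, applies the
#' kind-specific cutoff, and aggregates: occupancy is the fraction of
#' evaluable frames satisfying the criterion; on a single-frame model the
#' record is stable when the distance criterion holds, on an ensemble when
#' occupancy reaches the persistence threshold. Frames in which a required
#' atom is missing are excluded from the denominator, not counted as
#' non-bonded.
#'
#' @param model a `complex_model`
#' @param pair an [atom_group_pair()]
#' @param criteria an [interaction_criteria()]
#' @return an `interaction_record` with fields `pair`, `distance_series`,
#'   `occupancy`, `stable`, `n_evaluable_frames`, `single_frame`
#' @export
detect_interaction <- function(model, pair, criteria = interaction_criteria()) {
  d <- .group_distance_series(model, pair)
  cutoff <- if (pair$kind == "hbond") criteria$hbond_max_dist
            else criteria$saltbridge_max_dist
  ok <- d <= cutoff
  if (pair$kind == "hbond" && !is.null(criteria$hbond_min_angle))
    ok <- ok & .hbond_angle_pass(model, pair, criteria$hbond_min_angle)
  n_eval <- sum(!is.na(d))
  if (n_eval == 0L)
    stop(sprintf("no evaluable frames for pair '%s' (missing atoms)",
                 pair$label), call. = FALSE)
  occ <- mean(ok, na.rm = TRUE)
  single <- n_frames(model) == 1L
  stable <- if (single) isTRUE(ok[1L]) else occ >= criteria$persistence_stable_min
  structure(list(pair = pair, distance_series = d, occupancy = occ,
                 stable = stable, n_evaluable_frames = n_eval,
                 single_frame = single, cutoff = cutoff),
            class = "interaction_record")
}

# Optional donor-H-acceptor angle filter; passes frames where some hydrogen
# bonded to a group_a atom makes an angle >= min_angle with some group_b atom.
# Models without hydrogens pass everything (the criterion stays heavy-atom).
.hbond_angle_pass <- function(model, pair, min_angle) {
  nf <- n_frames(model)
  a <- model$atoms
  hyd <- which(a$elesy == "H")
  if (length(hyd) == 0L) return(rep(TRUE, nf))
  ia <- .group_indices(model, pair$group_a)
  ib <- .group_indices(model, pair$group_b)
  if (is.null(ia) || is.null(ib)) return(rep(TRUE, nf))
  pass <- rep(FALSE, nf)
  for (f in seq_len(nf)) {
    x <- frame_coords(model, f)
    for (i in ia) {
      dh <- hyd[sqrt(colSums((t(x[hyd, , drop = FALSE]) - x[i, ])^2)) < 1.25]
      if (length(dh) == 0L) next
      for (h in dh) for (j in ib) {
        if (.angle3(x[i, ], x[h, ], x[j, ]) >= min_angle) pass[f] <- TRUE
      }
    }
    # acceptor-side donors: allow group_b to donate as well
    for (j in ib) {
      dh <- hyd[sqrt(colSums((t(x[hyd, , drop = FALSE]) - x[j, ])^2)) < 1.25]
      if (length(dh) == 0L) next
      for (h in dh) for (i in ia) {
        if (.angle3(x[j, ], x[h, ], x[i, ]) >= min_angle) pass[f] <- TRUE
      }
    }
  }
  pass
}

# ---- candidate enumeration ---------------------------------------------

# side-chain heavy-atom H-bond donors/acceptors by residue type
.POLAR_SIDECHAIN <- list(
  SER = "OG", THR = "OG1", CYS = "SG", TYR = "OH",
  ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2"), TRP = "NE1",
  PTR = c("O1P", "O2P", "O3P"))

# charged groups for salt bridges
.CATIONIC_GROUP <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
.ANIONIC_GROUP <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                       PTR = c("O1P", "O2P", "O3P"))

.group_df <- function(chain, resno, elety, insert = "") {
  data.frame(chain = chain, resno = resno, insert = insert, elety = elety,
             stringsAsFactors = FALSE)
}

# any-frame minimum distance between two atom index sets, for the 6 A
# prefilter (a performance device; correctness is the full scan)
.anyframe_min_dist <- function(model, ia, ib) {
  best <- Inf
  for (i in ia) {
    xi <- model$xyz[, .xyz_cols(i), drop = FALSE]
    for (j in ib) {
      d2 <- min(rowSums((xi - model$xyz[, .xyz_cols(j), drop = FALSE])^2))
      best <- min(best, d2)
    }
  }
  sqrt(best)
}

.offset_label <- function(off) sprintf("%+d", off)

.dom_res_label <- function(model, dom, resno) {
  a <- model$atoms
  i <- which(a$chain == dom$chain & a$resno == resno)[1L]
  one <- .aa321(a$resid[i])
  lab <- .sh2_label_of(dom, resno)
  sprintf("%s%d%s", one, resno, if (nzchar(lab)) sprintf(" (%s)", lab) else "")
}

.aa321 <- function(resid) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V", PTR = "pY")
  out <- tab[resid]
  out[is.na(out)] <- resid[is.na(out)]
  unname(out)
}

#' Enumerate candidate interface interactions
#'
#' Builds the candidate atom-group pairs for one of three catalogs:
#' * `backbone` - peptide backbone N/O against domain backbone N/O (donor
#'   against acceptor, i.e. N-O combinations only), restricted to pairs that
#'   come within 6 Angstrom in at least one frame;
#' * `pY_pocket` - the pY phosphate oxygens against the canonical pocket
#'   probes: H-bonds to S34 Oγ (βB7), the K35 (BC1) and S36 (BC2) backbone
#'   amides and T42 Oγ1 (βC3), and salt bridges to the R32 (βB5) guanidinium
#'   and the K35/K55 ammonium groups (no prefilter; the list is fixed);
#' * `sidechain` - peptide side-chain donors/acceptors and charged groups
#'   against domain polar atoms (side-chain polar plus backbone N/O), within
#'   6 Angstrom in some frame; charged-charged combinations become
#'   salt-bridge group pairs, the rest individual H-bond pairs. The pY is
#'   excluded here (it has its own catalog).
#'
#' Ordering is deterministic: peptide offset, then domain residue number,
#' then atom names.
#'
#' @param model a `complex_model`
#' @param pep a `peptide_annotation`
#' @param dom an `sh2_annotation`
#' @param mode `"backbone"`, `"pY_pocket"` or `"sidechain"`
#' @param prefilter_dist any-frame distance prefilter, Angstrom
#' @return list of [atom_group_pair()] (possibly empty)
#' @export
enumerate_candidate_pairs <- function(model, pep, dom,
                                      mode = c("backbone", "pY_pocket",
                                               "sidechain"),
                                      prefilter_dist = 6.0) {
  mode <- match.arg(mode)
  switch(mode,
         backbone = .enumerate_backbone(model, pep, dom, prefilter_dist),
         pY_pocket = .enumerate_pocket(model, pep, dom),
         sidechain = .enumerate_sidechain(model, pep, dom, prefilter_dist))
}

.enumerate_backbone <- function(model, pep, dom, prefilter_dist) {
  a <- model$atoms
  dom_res <- sort(unique(a$resno[a$chain == dom$chain]))
  pairs <- list()
  for (k in order(pep$offset)) {
    off <- pep$offset[k]
    for (pat in c("N", "O")) {
      ip <- atom_indices(model, chain = pep$chain[k], resno = pep$resno[k],
                         elety = pat, insert = pep$insert[k])
      if (length(ip) == 0L) next
      dat <- if (pat == "N") "O" else "N"
      for (rn in dom_res) {
        id <- atom_indices(model, chain = dom$chain, resno = rn, elety = dat)
        if (length(id) == 0L) next
        if (.anyframe_min_dist(model, ip, id[1L]) > prefilter_dist) next
        lab <- sprintf("%s %s : %s %s", .offset_label(off), pat,
                       .dom_res_label(model, dom, rn), dat)
        pairs[[length(pairs) + 1L]] <- atom_group_pair(
          lab,
          .group_df(pep$chain[k], pep$resno[k], pat, pep$insert[k]),
          .group_df(dom$chain, rn, dat),
          kind = "hbond")
      }
    }
  }
  pairs
}

.enumerate_pocket <- function(model, pep, dom) {
  py <- attr(pep, "py")
  phos <- .group_df(py$chain, py$resno, c("O1P", "O2P", "O3P"), py$insert)
  probe <- function(lbl, elety) {
    rr <- sh2_residue(model, dom, lbl)
    .group_df(rr$chain, rr$resno, elety, rr$insert)
  }
  mk <- function(lbl, elety, kind, what) {
    rr <- sh2_residue(model, dom, lbl)
    atom_group_pair(
      sprintf("pY phosphate : %s %s", .dom_res_label(model, dom, rr$resno), what),
      phos, probe(lbl, elety), kind = kind)
  }
  list(
    mk("βB7", "OG", "hbond", "OG"),          # S34 side-chain hydroxyl
    mk("BC1", "N", "hbond", "N"),            # K35 backbone amide
    mk("BC2", "N", "hbond", "N"),            # S36 backbone amide
    mk("βC3", "OG1", "hbond", "OG1"),        # T42 side-chain hydroxyl
    mk("βB5", c("NE", "NH1", "NH2"), "saltbridge", "guanidinium"),  # R32
    mk("BC1", "NZ", "saltbridge", "NZ"),     # K35 ammonium
    mk("βD6", "NZ", "saltbridge", "NZ"))     # K55 ammonium
}

.enumerate_sidechain <- function(model, pep, dom, prefilter_dist) {
  a <- model$atoms
  dom_res <- sort(unique(a$resno[a$chain == dom$chain]))
  dom_resid <- vapply(dom_res, function(rn)
    a$resid[which(a$chain == dom$chain & a$resno == rn)[1L]], "")
  pairs <- list()
  for (k in order(pep$offset)) {
    off <- pep$offset[k]
    if (off == 0L) next  # pY handled by the pocket catalog
    p_resid <- pep$resid[k]
    p_polar <- .POLAR_SIDECHAIN[[p_resid]]
    p_cat <- .CATIONIC_GROUP[[p_resid]]
    p_ani <- .ANIONIC_GROUP[[p_resid]]
    p_one <- .aa321(p_resid)
    # hbond candidates: each peptide polar side-chain atom vs each domain
    # polar atom (side-chain polar + backbone N/O)
    for (pat in p_polar) {
      ip <- atom_indices(model, chain = pep$chain[k], resno = pep$resno[k],
                         elety = pat, insert = pep$insert[k])
      if (length(ip) == 0L) next
      for (di in seq_along(dom_res)) {
        rn <- dom_res[di]
        d_atoms <- c(.POLAR_SIDECHAIN[[dom_resid[di]]], "N", "O")
        for (dat in d_atoms) {
          id <- atom_indices(model, chain = dom$chain, resno = rn, elety = dat)
          if (length(id) == 0L) next
          if (.anyframe_min_dist(model, ip, id[1L]) > prefilter_dist) next
          lab <- sprintf("%s %s-%s : %s %s", .offset_label(off), p_one, pat,
                         .dom_res_label(model, dom, rn), dat)
          pairs[[length(pairs) + 1L]] <- atom_group_pair(
            lab,
            .group_df(pep$chain[k], pep$resno[k], pat, pep$insert[k]),
            .group_df(dom$chain, rn, dat),
            kind = "hbond")
        }
      }
    }
    # salt-bridge candidates: peptide charged group vs oppositely charged
    # domain groups
    pg <- if (!is.null(p_cat)) list(group = p_cat, against = .ANIONIC_GROUP)
          else if (!is.null(p_ani)) list(group = p_ani, against = .CATIONIC_GROUP)
          else NULL
    if (!is.null(pg)) {
      ip <- .group_indices(model, .group_df(pep$chain[k], pep$resno[k],
                                            pg$group, pep$insert[k]))
      if (!is.null(ip)) {
        for (di in seq_along(dom_res)) {
          rn <- dom_res[di]
          g <- pg$against[[dom_resid[di]]]
          if (is.null(g)) next
          id <- .group_indices(model, .group_df(dom$chain, rn, g))
          if (is.null(id)) next
          if (.anyframe_min_dist(model, ip, id) > prefilter_dist) next
          lab <- sprintf("%s %s : %s [salt bridge]", .offset_label(off), p_one,
                         .dom_res_label(model, dom, rn))
          pairs[[length(pairs) + 1L]] <- atom_group_pair(
            lab,
            .group_df(pep$chain[k], pep$resno[k], pg$group, pep$insert[k]),
            .group_df(dom$chain, rn, g),
            kind = "saltbridge")
        }
      }
    }
  }
  pairs
}

#' Histogram of an interaction distance series
#'
#' Normalized (density) histogram of the per-frame distances, with the 4
#' Angstrom salt-bridge reference marker carried as attribute `reference`.
#'
#' @param record an `interaction_record`
#' @param bin_width bin width in Angstrom
#' @return data frame with `bin_left`, `bin_right`, `density`
#' @export
distance_distribution <- function(record, bin_width = 0.1) {
  if (bin_width <= 0) stop("bin width must be positive", call. = FALSE)
  d <- record$distance_series[!is.na(record$distance_series)]
  if (length(d) == 0L) stop("no evaluable frames", call. = FALSE)
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  out <- data.frame(bin_left = utils::head(h$breaks, -1L),
                    bin_right = utils::tail(h$breaks, -1L),
                    density = h$density)
  attr(out, "reference") <- 4.0
  out
}

# ---- table rendering ----------------------------------------------------

.format_cell <- function(record, criteria) {
  d <- record$distance_series
  if (all(is.na(d))) return(list(cell = "n.a.", stable = NA, value = NA_real_))
  if (record$single_frame) {
    val <- .round_half_up(d[1L], 1L)
    if (record$pair$kind == "hbond" && !record$stable)
      return(list(cell = "-", stable = FALSE, value = val))
    list(cell = sprintf("%.1f", val), stable = record$stable, value = val)
  } else {
    pct <- .round_half_up(100 * record$occupancy, 0L)
    if (record$occupancy < criteria$report_min)
      return(list(cell = "-", stable = FALSE, value = pct))
    list(cell = sprintf("%d", as.integer(pct)), stable = record$stable,
         value = pct)
  }
}

#' Render an interaction catalog as a table
#'
#' One row per model, one column per pair label, following the print
#' conventions of interface tables: single structures report the distance in
#' Angstrom to one decimal (H-bonds beyond the cutoff print as `-`,
#' salt-bridge distances are always shown), ensembles report integer percent
#' persistence with `-` below the reporting threshold; records whose atoms
#' are missing print `n.a.`. Stability flags (distance within cutoff, or
#' persistence at least 50%) are attached as the logical attribute `stable`,
#' numeric cell values as attribute `values`.
#'
#' @param records a list of `interaction_record` sharing one model, or a
#'   named list of such lists (one element per model/row)
#' @param criteria an [interaction_criteria()]
#' @return a character data frame (rows = models, columns = pair labels)
#' @export
build_interaction_table <- function(records, criteria = interaction_criteria()) {
  if (length(records) > 0L && inherits(records[[1L]], "interaction_record"))
    records <- list(model = records)
  labels <- unique(unlist(lapply(records, function(rl)
    vapply(rl, function(r) r$pair$label, ""))))
  tab <- matrix("n.a.", nrow = length(records), ncol = length(labels),
                dimnames = list(names(records), labels))
  stable <- matrix(NA, nrow = length(records), ncol = length(labels),
                   dimnames = dimnames(tab))
  values <- matrix(NA_real_, nrow = length(records), ncol = length(labels),
                   dimnames = dimnames(tab))
  for (m in seq_along(records)) {
    for (r in records[[m]]) {
      fc <- .format_cell(r, criteria)
      tab[m, r$pair$label] <- fc$cell
      stable[m, r$pair$label] <- fc$stable
      values[m, r$pair$label] <- fc$value
    }
  }
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  attr(out, "stable") <- stable
  attr(out, "values") <- values
  out
}
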