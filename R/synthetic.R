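# Idealized internal coordinates for heavy-atom side chains. Each row places
# one atom from three previously placed atoms of the same residue:
# (a, b, c, bond, angle b-c-new, dihedral a-b-c-new). Rows with base "chi"
# take the dihedral chi1_default + dih; "abs" rows are fixed. The geometry is
# deliberately simple (no ring closure constraints, no force field): the
# generator's claim is correct atom names, bonded topology and tunable chi1,
# not thermodynamic realism.
.tpl_row <- function(name, a, b, c, bond, angle, base, dih) {
  data.frame(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
             base = base, dih = dih, stringsAsFactors = FALSE)
}

.sidechain_template <- local({
  r <- .tpl_row
  phe_core <- rbind(
    r("CG", "N", "CA", "CB", 1.502, 113.8, "chi", 0),
    r("CD1", "CA", "CB", "CG", 1.384, 120.8, "abs", 90),
    r("CD2", "CA", "CB", "CG", 1.384, 120.8, "abs", -90),
    r("CE1", "CB", "CG", "CD1", 1.382, 120.7, "abs", 180),
    r("CE2", "CB", "CG", "CD2", 1.382, 120.7, "abs", 180),
    r("CZ", "CG", "CD1", "CE1", 1.382, 120.0, "abs", 0))
  tyr <- rbind(phe_core, r("OH", "CD1", "CE1", "CZ", 1.376, 119.9, "abs", 180))
  list(
    GLY = NULL,
    ALA = NULL,  # CB is added for every non-Gly residue
    SER = r("OG", "N", "CA", "CB", 1.417, 110.8, "chi", 0),
    CYS = r("SG", "N", "CA", "CB", 1.808, 113.8, "chi", 0),
    THR = rbind(r("OG1", "N", "CA", "CB", 1.433, 109.6, "chi", 0),
                r("CG2", "N", "CA", "CB", 1.521, 110.5, "chi", -122)),
    VAL = rbind(r("CG1", "N", "CA", "CB", 1.540, 110.5, "chi", 0),
                r("CG2", "N", "CA", "CB", 1.540, 110.5, "chi", 122)),
    ILE = rbind(r("CG1", "N", "CA", "CB", 1.530, 110.4, "chi", 0),
                r("CG2", "N", "CA", "CB", 1.521, 110.5, "chi", -122),
                r("CD1", "CA", "CB", "CG1", 1.513, 113.8, "abs", 180)),
    LEU = rbind(r("CG", "N", "CA", "CB", 1.530, 116.3, "chi", 0),
                r("CD1", "CA", "CB", "CG", 1.521, 110.7, "abs", 180),
                r("CD2", "CA", "CB", "CG", 1.521, 110.7, "abs", 60)),
    ASP = rbind(r("CG", "N", "CA", "CB", 1.516, 112.6, "chi", 0),
                r("OD1", "CA", "CB", "CG", 1.249, 118.4, "abs", -30),
                r("OD2", "CA", "CB", "CG", 1.249, 118.4, "abs", 150)),
    ASN = rbind(r("CG", "N", "CA", "CB", 1.516, 112.6, "chi", 0),
                r("OD1", "CA", "CB", "CG", 1.231, 120.8, "abs", -30),
                r("ND2", "CA", "CB", "CG", 1.328, 116.4, "abs", 150)),
    GLU = rbind(r("CG", "N", "CA", "CB", 1.530, 114.1, "chi", 0),
                r("CD", "CA", "CB", "CG", 1.516, 112.6, "abs", 180),
                r("OE1", "CB", "CG", "CD", 1.249, 118.4, "abs", -30),
                r("OE2", "CB", "CG", "CD", 1.249, 118.4, "abs", 150)),
    GLN = rbind(r("CG", "N", "CA", "CB", 1.530, 114.1, "chi", 0),
                r("CD", "CA", "CB", "CG", 1.516, 112.6, "abs", 180),
                r("OE1", "CB", "CG", "CD", 1.231, 120.8, "abs", -30),
                r("NE2", "CB", "CG", "CD", 1.328, 116.4, "abs", 150)),
    LYS = rbind(r("CG", "N", "CA", "CB", 1.530, 114.1, "chi", 0),
                r("CD", "CA", "CB", "CG", 1.530, 111.3, "abs", 180),
                r("CE", "CB", "CG", "CD", 1.530, 111.3, "abs", 180),
                r("NZ", "CG", "CD", "CE", 1.489, 111.9, "abs", 180)),
    ARG = rbind(r("CG", "N", "CA", "CB", 1.530, 114.1, "chi", 0),
                r("CD", "CA", "CB", "CG", 1.530, 111.3, "abs", 180),
                r("NE", "CB", "CG", "CD", 1.461, 112.0, "abs", 180),
                r("CZ", "CG", "CD", "NE", 1.329, 124.2, "abs", 180),
                r("NH1", "CD", "NE", "CZ", 1.326, 120.0, "abs", 0),
                r("NH2", "CD", "NE", "CZ", 1.326, 120.0, "abs", 180)),
    MET = rbind(r("CG", "N", "CA", "CB", 1.530, 114.1, "chi", 0),
                r("SD", "CA", "CB", "CG", 1.803, 112.7, "abs", 180),
                r("CE", "CB", "CG", "SD", 1.791, 100.9, "abs", 180)),
    PHE = phe_core,
    TYR = tyr,
    PTR = rbind(tyr,
                r("P", "CE1", "CZ", "OH", 1.610, 118.5, "abs", 180),
                r("O1P", "CZ", "OH", "P", 1.480, 105.0, "abs", 60),
                r("O2P", "CZ", "OH", "P", 1.480, 105.0, "abs", 180),
                r("O3P", "CZ", "OH", "P", 1.480, 105.0, "abs", -60)),
    TRP = rbind(r("CG", "N", "CA", "CB", 1.498, 113.6, "chi", 0),
                r("CD1", "CA", "CB", "CG", 1.365, 126.9, "abs", 90),
                r("CD2", "CA", "CB", "CG", 1.433, 126.7, "abs", -90),
                r("NE1", "CB", "CG", "CD1", 1.374, 110.2, "abs", 180),
                r("CE2", "CB", "CG", "CD2", 1.409, 107.2, "abs", 180),
                r("CE3", "CB", "CG", "CD2", 1.398, 133.9, "abs", 0),
                r("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, "abs", 180),
                r("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, "abs", 180),
                r("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, "abs", 0)),
    HIS = rbind(r("CG", "N", "CA", "CB", 1.497, 113.8, "chi", 0),
                r("ND1", "CA", "CB", "CG", 1.378, 122.7, "abs", 90),
                r("CD2", "CA", "CB", "CG", 1.356, 131.2, "abs", -90),
                r("CE1", "CB", "CG", "ND1", 1.321, 109.3, "abs", 180),
                r("NE2", "CB", "CG", "CD2", 1.374, 107.2, "abs", 180)),
    PRO = rbind(r("CG", "N", "CA", "CB", 1.492, 104.5, "chi", 0),
                r("CD", "CA", "CB", "CG", 1.503, 106.1, "abs", -30)))
})

.RESIDUE_TEMPLATES <- .sidechain_template

.AA_1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# element symbol from a heavy-atom name
.elesy_from_name <- function(elety) substr(gsub("[0-9]", "", elety), 1L, 1L)

#' @noRd
#' Build an all-heavy-atom peptide chain in a repeated (phi, psi) backbone
#' conformation with idealized side chains at chi1 = chi1_default.
#' Returns list(coords, elety, resid, resno, elesy, chain).
.build_peptide_atoms <- function(resids, chain, start_resno, phi = -120,
                                 psi = 130, chi1_default = -60,
                                 origin = c(0, 0, 0)) {
  nres <- length(resids)
  # backbone trace
  bb <- vector("list", nres)
  n1 <- c(0, 0, 0)
  ca1 <- c(1.458, 0, 0)
  ang <- .deg2rad(111.2)
  c1 <- ca1 + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  bb[[1L]] <- list(N = n1, CA = ca1, C = c1)
  for (i in seq_len(nres - 1L)) {
    p <- bb[[i]]
    n_next <- .place_atom(p$N, p$CA, p$C, 1.329, 116.2, psi)
    ca_next <- .place_atom(p$CA, p$C, n_next, 1.458, 121.7, 180)
    c_next <- .place_atom(p$C, n_next, ca_next, 1.525, 111.2, phi)
    bb[[i + 1L]] <- list(N = n_next, CA = ca_next, C = c_next)
  }
  coords <- list(); elety <- character(); resno_v <- integer(); resid_v <- character()
  for (i in seq_len(nres)) {
    p <- bb[[i]]
    placed <- list(N = p$N, CA = p$CA, C = p$C)
    # carbonyl O anti to the next amide nitrogen
    placed$O <- .place_atom(p$N, p$CA, p$C, 1.231, 120.5, psi + 180)
    rtype <- resids[i]
    if (rtype != "GLY") {
      placed$CB <- .place_atom(p$N, p$C, p$CA, 1.530, 110.1, 122.5)
      tpl <- .sidechain_template[[rtype]]
      if (!is.null(tpl)) {
        for (k in seq_len(nrow(tpl))) {
          row <- tpl[k, ]
          dih <- if (row$base == "chi") chi1_default + row$dih else row$dih
          placed[[row$name]] <- .place_atom(placed[[row$a]], placed[[row$b]],
                                            placed[[row$c]], row$bond,
                                            row$angle, dih)
        }
      }
    }
    for (nm in names(placed)) {
      coords[[length(coords) + 1L]] <- placed[[nm]]
      elety <- c(elety, nm)
      resno_v <- c(resno_v, start_resno + i - 1L)
      resid_v <- c(resid_v, rtype)
    }
  }
  xyz <- do.call(rbind, coords)
  xyz <- sweep(xyz, 2, origin, `+`)
  list(coords = xyz, elety = elety, resid = resid_v, resno = resno_v,
       elesy = .elesy_from_name(elety), chain = rep(chain, length(elety)))
}

# residue identities of the SHP2 N-SH2 scaffold at the annotated positions;
# everything else is glycine backbone
.SCAFFOLD_RESID <- c(
  `13` = "GLY", `14` = "VAL", `32` = "ARG", `34` = "SER", `35` = "LYS",
  `36` = "SER", `40` = "ASP", `42` = "THR", `51` = "VAL", `52` = "THR",
  `53` = "HIS", `54` = "ILE", `55` = "LYS", `57` = "GLN", `65` = "LEU",
  `68` = "GLY", `81` = "TYR", `86` = "GLN", `87` = "GLY", `88` = "LEU",
  `89` = "LYS", `90` = "GLU", `91` = "LYS", `92` = "ASN", `96` = "ILE")

#' Build a deterministic synthetic domain-peptide complex
#'
#' Constructs an all-heavy-atom toy complex: the phosphopeptide in an
#' extended backbone conformation (phi, psi = -120, 130, the bound-state
#' geometry of type-II SH2 complexes) and, 15 Angstrom away, a rigid
#' scaffold "domain" spanning residues 3-103 whose annotated positions carry
#' the real SHP2 N-SH2 residue types (R32, S34, K35, S36, D40, T42, K55,
#' Q57, K89, K91, ...), so that every structural label and probe atom used
#' downstream resolves. The scaffold is deliberately not a folded SH2 - the
#' metrics consume geometry, and contacts are engineered per frame by
#' [sample_ensemble()]. The builder is deterministic: identical config gives
#' bit-identical coordinates.
#'
#' @param config list with `peptide` (1-letter sequence; mark the
#'   phosphotyrosine either as lowercase `"y"` or via `py_index`), optional
#'   `py_index`, `peptide_chain` (default `"B"`), `domain_chain` (`"A"`),
#'   `peptide_start_resno` (1), `domain_residues` (3:103), `domain_offset`
#'   (c(0, 15, 0)), `domain_placements` (list of `list(resno, delta)` rigid
#'   translations of single scaffold residues)
#' @return a single-frame `complex_model`
#' @export
build_template_complex <- function(config) {
  stopifnot(is.list(config), !is.null(config$peptide))
  seq1 <- strsplit(config$peptide, "")[[1L]]
  py_index <- config$py_index
  if (is.null(py_index)) py_index <- which(seq1 == "y")
  if (length(py_index) != 1L)
    stop("peptide must contain exactly one phosphotyrosine (lowercase 'y' or py_index)",
         call. = FALSE)
  if (!toupper(seq1[py_index]) == "Y")
    stop("py_index does not point at a tyrosine", call. = FALSE)
  resids <- unname(.AA_1TO3[toupper(seq1)])
  if (anyNA(resids)) stop("unknown residue letter in peptide", call. = FALSE)
  resids[py_index] <- "PTR"
  pep_chain <- config$peptide_chain %||% "B"
  dom_chain <- config$domain_chain %||% "A"
  start <- config$peptide_start_resno %||% 1L
  dom_res <- config$domain_residues %||% 3:103
  offset <- config$domain_offset %||% c(0, 15, 0)

  pep <- .build_peptide_atoms(resids, pep_chain, start)
  dom_resids <- ifelse(as.character(dom_res) %in% names(.SCAFFOLD_RESID),
                       .SCAFFOLD_RESID[as.character(dom_res)], "GLY")
  dom <- .build_peptide_atoms(unname(dom_resids), dom_chain, min(dom_res),
                              origin = offset)
  # scaffold residue numbers may be non-consecutive
  dom$resno <- dom_res[match(dom$resno - min(dom_res) + 1L,
                             seq_along(dom_res))]
  for (pl in config$domain_placements %||% list()) {
    sel <- dom$resno == pl$resno
    dom$coords[sel, ] <- sweep(dom$coords[sel, , drop = FALSE], 2,
                               pl$delta, `+`)
  }
  atoms <- data.frame(
    eleno = seq_along(c(dom$elety, pep$elety)),
    elety = c(dom$elety, pep$elety),
    resid = c(dom$resid, pep$resid),
    chain = c(dom$chain, pep$chain),
    resno = c(dom$resno, pep$resno),
    insert = "",
    elesy = c(dom$elesy, pep$elesy),
    stringsAsFactors = FALSE)
  xyz <- matrix(t(rbind(dom$coords, pep$coords)), nrow = 1L)
  .new_complex_model(atoms, xyz, dom_chain, pep_chain, "synthetic template")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Von Mises random angles (degrees)
#'
#' Best-Fisher rejection sampling of the von Mises distribution on the
#' circle; `kappa = 0` degenerates to the circular uniform. The mean
#' resultant length of the distribution is the Bessel ratio
#' `I1(kappa) / I0(kappa)`, the oracle used to test order-parameter
#' recovery. No installed package provides this sampler.
#'
#' @param n number of draws
#' @param mu mean direction, degrees
#' @param kappa concentration (>= 0)
#' @return angles in degrees, wrapped to (-180, 180]
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa < 1e-8) return(.wrap180(stats::runif(n, -180, 180)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  .wrap180(.rad2deg(out) + mu)
}

#' @noRd
#' Draw from a circular distribution spec:
#' list(type = "point", mu), list(type = "vonmises", mu, kappa),
#' list(type = "mixture", weights, components = list(...)).
.draw_circular <- function(n, dist) {
  switch(dist$type,
         point = rep(dist$mu, n),
         vonmises = rvonmises(n, dist$mu, dist$kappa),
         mixture = {
           k <- sample.int(length(dist$components), n, replace = TRUE,
                           prob = dist$weights)
           out <- numeric(n)
           for (j in seq_along(dist$components)) {
             sel <- k == j
             if (any(sel))
               out[sel] <- .draw_circular(sum(sel), dist$components[[j]])
           }
           out
         },
         stop(sprintf("unknown circular distribution '%s'", dist$type),
              call. = FALSE))
}

#' Contact specification for the synthetic ensemble
#'
#' @param pair an [atom_group_pair()] (group_b must lie within a single
#'   residue, which is rigidly repositioned per frame)
#' @param occupancy target bound probability per frame, in `[0, 1]`
#' @param bound_distance,unbound_distance engineered minimum cross-group
#'   distance in the bound / unbound state, Angstrom (bound must be within
#'   the detection cutoff, unbound beyond it)
#' @return a `contact_spec`
#' @export
contact_spec <- function(pair, occupancy, bound_distance = 2.9,
                         unbound_distance = 6.5) {
  stopifnot(inherits(pair, "atom_group_pair"),
            occupancy >= 0, occupancy <= 1,
            bound_distance > 0, bound_distance < unbound_distance)
  cutoff <- if (pair$kind == "hbond") 3.5 else 4.0
  if (bound_distance > cutoff || unbound_distance <= cutoff)
    stop(sprintf("need bound <= %.1f A < unbound for a %s contact",
                 cutoff, pair$kind), call. = FALSE)
  if (length(unique(pair$group_b$resno)) != 1L)
    stop("group_b must lie within a single residue", call. = FALSE)
  structure(list(pair = pair, occupancy = occupancy,
                 bound_distance = bound_distance,
                 unbound_distance = unbound_distance),
            class = "contact_spec")
}

#' Synthetic ensemble specification
#'
#' Defines the ground truth of a generated ensemble: per-contact two-state
#' geometry switching with prescribed occupancies, per-residue chi1 drawn
#' from prescribed circular distributions, and isotropic Gaussian positional
#' noise. Contacts are temporally i.i.d. by default; `markov_dwell` (mean
#' dwell time in frames) switches to a two-state Markov chain with the same
#' stationary occupancy, producing the autocorrelation that makes
#' block-averaging diagnostics informative.
#'
#' @param template single-frame `complex_model` from [build_template_complex()]
#' @param n_frames number of frames to generate
#' @param seed RNG seed (the generator is fully reproducible)
#' @param contacts list of [contact_spec()]
#' @param dihedrals list of `list(residue = residue_ref, dist = <circular
#'   distribution spec>)`
#' @param noise_sigma isotropic positional noise sd per coordinate, Angstrom
#' @param markov_dwell optional mean dwell time (frames) for Markov switching
#' @return a `synthetic_ensemble_spec`
#' @export
synthetic_ensemble_spec <- function(template, n_frames, seed,
                                    contacts = list(), dihedrals = list(),
                                    noise_sigma = 0.1, markov_dwell = NULL) {
  stopifnot(inherits(template, "complex_model"), n_frames >= 1L,
            noise_sigma >= 0)
  # conflicting contact specs: no two contacts may reposition atoms of the
  # same residue
  moved <- vapply(contacts, function(cs)
    paste(cs$pair$group_b$chain[1L], cs$pair$group_b$resno[1L]), "")
  if (anyDuplicated(moved))
    stop("conflicting contact specs: several contacts reposition the same residue",
         call. = FALSE)
  structure(list(template = template, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), contacts = contacts,
                 dihedrals = dihedrals, noise_sigma = noise_sigma,
                 markov_dwell = markov_dwell),
            class = "synthetic_ensemble_spec")
}

# two-state {0,1} chain with stationary P(1) = p; `dwell` scales the
# correlation time (leave rates q01 = p/dwell, q10 = (1-p)/dwell)
.markov_states <- function(n, p, dwell) {
  q01 <- min(1, p / dwell)
  q10 <- min(1, (1 - p) / dwell)
  s <- integer(n)
  s[1L] <- stats::rbinom(1L, 1L, p)
  for (i in 2:n) {
    s[i] <- if (s[i - 1L] == 1L) {
      if (stats::runif(1) < q10) 0L else 1L
    } else {
      if (stats::runif(1) < q01) 1L else 0L
    }
  }
  s
}

#' Sample a synthetic ensemble
#'
#' Generates `n_frames` frames from the template: each contact is
#' independently bound with its prescribed probability (the group_b residue
#' is rigidly translated along the line of closest approach so the minimum
#' cross-group distance equals the bound / unbound distance), each chi1 spec
#' is drawn from its circular distribution and applied by rotating the side
#' chain about the CA-CB axis, and isotropic Gaussian jitter is added to all
#' atoms. The realized per-frame states and drawn angles are returned as the
#' ground-truth record, enabling closed-loop recovery tests.
#'
#' @param spec a [synthetic_ensemble_spec()]
#' @return list with `model` (multi-frame `complex_model`) and `truth`
#'   (list: `contact_states` frames x contacts logical matrix,
#'   `contact_occupancy`, `chi1_draws` frames x dihedrals matrix in degrees)
#' @export
sample_ensemble <- function(spec) {
  tmpl <- spec$template
  x0 <- frame_coords(tmpl, 1L)
  nf <- spec$n_frames
  na <- n_atoms(tmpl)
  nc <- length(spec$contacts)
  nd <- length(spec$dihedrals)

  # per-contact atom indexing (resolved once)
  cinfo <- lapply(spec$contacts, function(cs) {
    ia <- .group_indices(tmpl, cs$pair$group_a)
    ib <- .group_indices(tmpl, cs$pair$group_b)
    if (is.null(ia) || is.null(ib))
      stop(sprintf("contact '%s': atoms missing from template", cs$pair$label),
           call. = FALSE)
    res_b <- atom_indices(tmpl, chain = cs$pair$group_b$chain[1L],
                          resno = cs$pair$group_b$resno[1L],
                          insert = cs$pair$group_b$insert[1L])
    list(ia = ia, ib = ib, res_b = res_b)
  })
  # per-dihedral atom indexing
  dinfo <- lapply(spec$dihedrals, function(ds) {
    r <- ds$residue
    i <- atom_indices(tmpl, chain = r$chain, resno = r$resno,
                      insert = r$insert)
    resid <- tmpl$atoms$resid[i[1L]]
    gamma <- .CHI1_GAMMA[[resid]]
    if (is.null(gamma))
      stop(sprintf("residue %s %d has no chi1", r$chain, r$resno),
           call. = FALSE)
    at <- function(nm) i[tmpl$atoms$elety[i] == nm][1L]
    core <- c(N = at("N"), CA = at("CA"), CB = at("CB"), G = at(gamma))
    if (anyNA(core))
      stop(sprintf("residue %s %d lacks chi1 atoms", r$chain, r$resno),
           call. = FALSE)
    distal <- i[!tmpl$atoms$elety[i] %in% c("N", "CA", "C", "O", "CB")]
    distal <- distal[tmpl$atoms$elesy[distal] != "H"]
    list(core = core, distal = distal)
  })

  withr::with_seed(spec$seed, {
    states <- matrix(FALSE, nrow = nf, ncol = max(nc, 1L))
    if (nc > 0L) {
      for (j in seq_len(nc)) {
        p <- spec$contacts[[j]]$occupancy
        states[, j] <- if (is.null(spec$markov_dwell))
          stats::rbinom(nf, 1L, p) == 1L
        else .markov_states(nf, p, spec$markov_dwell) == 1L
      }
    }
    draws <- matrix(NA_real_, nrow = nf, ncol = max(nd, 1L))
    if (nd > 0L) {
      for (j in seq_len(nd))
        draws[, j] <- .draw_circular(nf, spec$dihedrals[[j]]$dist)
    }
    noise <- if (spec$noise_sigma > 0)
      array(stats::rnorm(nf * na * 3L, 0, spec$noise_sigma), c(nf, na, 3L))
    else NULL

    xyz <- matrix(0, nrow = nf, ncol = 3L * na)
    for (f in seq_len(nf)) {
      x <- x0
      for (j in seq_len(nd)) {
        di <- dinfo[[j]]
        cur <- .dihedral(x[di$core["N"], , drop = FALSE],
                         x[di$core["CA"], , drop = FALSE],
                         x[di$core["CB"], , drop = FALSE],
                         x[di$core["G"], , drop = FALSE])
        # right-hand rotation about CA->CB decreases the IUPAC dihedral
        delta <- cur - draws[f, j]
        x[di$distal, ] <- .rotate_about_axis(
          x[di$distal, , drop = FALSE],
          origin = x[di$core["CA"], ],
          axis = x[di$core["CB"], ] - x[di$core["CA"], ],
          theta = delta)
      }
      for (j in seq_len(nc)) {
        ci <- cinfo[[j]]
        cs <- spec$contacts[[j]]
        target <- if (states[f, j]) cs$bound_distance else cs$unbound_distance
        xa <- x[ci$ia, , drop = FALSE]
        xb <- x[ci$ib, , drop = FALSE]
        d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
        k <- arrayInd(which.min(d2), dim(d2))
        u <- xb[k[2L], ] - xa[k[1L], ]
        d0 <- sqrt(sum(u^2))
        x[ci$res_b, ] <- sweep(x[ci$res_b, , drop = FALSE], 2,
                               (target / d0 - 1) * u, `+`)
      }
      if (!is.null(noise)) x <- x + noise[f, , ]
      xyz[f, ] <- as.vector(t(x))
    }
    model <- tmpl
    model$xyz <- xyz
    model$source <- sprintf("synthetic ensemble (seed %d)", spec$seed)
    truth <- list(
      contact_states = if (nc > 0L) states[, seq_len(nc), drop = FALSE] else NULL,
      contact_occupancy = if (nc > 0L) colMeans(states[, seq_len(nc), drop = FALSE]) else NULL,
      chi1_draws = if (nd > 0L) draws[, seq_len(nd), drop = FALSE] else NULL,
      spec = spec[c("n_frames", "seed", "noise_sigma", "markov_dwell")])
    list(model = model, truth = truth)
  })
}
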