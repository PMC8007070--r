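# Fixtures are generated in code; nothing is read from disk. The "mini"
# scaffold keeps every annotated SH2 position (so build_sh2_annotation
# resolves) but drops the unannotated glycine filler, which makes ensemble
# generation several-fold faster.

.MINI_DOMAIN <- sort(unique(c(13, 14, 32, 34:38, 40, 42, 51:55, 57, 65:69,
                              81, 84:96)))

fixture_template <- function(peptide = "LNyIDLDL", mini = TRUE, ...) {
  config <- list(peptide = peptide,
                 domain_residues = if (mini) .MINI_DOMAIN else 3:103)
  extra <- list(...)
  config[names(extra)] <- extra
  build_template_complex(config)
}

# a bare-bones model built directly from coordinates, for geometric toys:
# `atoms` is a data.frame with chain/resno/elety (+ optional resid, insert,
# elesy); `frames` a list of n x 3 matrices.
toy_model <- function(atoms, frames, domain_chain = "A", peptide_chain = "B") {
  if (is.null(atoms$resid)) atoms$resid <- "GLY"
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$elesy))
    atoms$elesy <- substr(gsub("[0-9]", "", atoms$elety), 1, 1)
  atoms$eleno <- seq_len(nrow(atoms))
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  sh2pep:::.new_complex_model(atoms, xyz, domain_chain, peptide_chain, "toy")
}

# independent brute-force oracle: minimum cross distance by explicit loops
brute_min_dist <- function(xa, xb) {
  best <- Inf
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
    d <- sqrt(sum((xa[i, ] - xb[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# a standard salt-bridge pair on the fixture template: peptide +2 Asp
# carboxylate against the K91 ammonium
fixture_saltbridge_pair <- function() {
  atom_group_pair("+2 D : K91 [salt bridge]",
                  data.frame(chain = "B", resno = 5, elety = c("OD1", "OD2")),
                  data.frame(chain = "A", resno = 91, elety = "NZ"),
                  kind = "saltbridge")
}

# an H-bond pair: peptide +2 backbone O against the K91 backbone N
fixture_backbone_pair <- function() {
  atom_group_pair("+2 O : K91 N (BG7)",
                  data.frame(chain = "B", resno = 5, elety = "O"),
                  data.frame(chain = "A", resno = 91, elety = "N"),
                  kind = "hbond")
}
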