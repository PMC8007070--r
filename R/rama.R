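#' Ramachandran region polygons
#'
#' Region boundaries are configuration, not code: they are read from a CSV
#' shipped with the package (`extdata/rama_regions.csv`, columns `class`,
#' `region`, `vertex`, `phi`, `psi`), and a user file with the same layout
#' can be substituted. The default polygons are generous published-style
#' boxes for three residue classes (generic, Gly, Pro): the beta/extended
#' region (top-left quadrant), the right-handed alpha region, and the
#' left-handed alpha region (for the generic class mostly relevant to Gly).
#' Anything outside all polygons classifies as `"other"`.
#'
#' @param path optional CSV path overriding the packaged regions
#' @return a named list: per class, a named list of polygon matrices
#'   (columns `phi`, `psi`)
#' @export
rama_regions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rama_regions.csv", package = "sh2pep",
                        mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "region", "vertex", "phi", "psi") %in% names(df)))
  out <- list()
  for (cl in unique(df$class)) {
    sub <- df[df$class == cl, ]
    out[[cl]] <- lapply(split(sub, sub$region), function(s) {
      s <- s[order(s$vertex), ]
      cbind(phi = s$phi, psi = s$psi)
    })
  }
  out
}

#' Classify phi/psi pairs into Ramachandran regions
#'
#' @param phi,psi numeric vectors of dihedrals, degrees
#' @param residue_class `"generic"`, `"gly"` or `"pro"`
#' @param regions polygons from [rama_regions()]
#' @return character vector: `"beta_extended"`, `"alpha_R"`, `"alpha_L"` or
#'   `"other"` (first matching region in that order wins)
#' @export
classify_rama <- function(phi, psi,
                          residue_class = c("generic", "gly", "pro"),
                          regions = rama_regions()) {
  residue_class <- match.arg(residue_class)
  polys <- regions[[residue_class]]
  if (is.null(polys)) polys <- regions[["generic"]]
  pts <- cbind(phi, psi)
  out <- rep("other", length(phi))
  for (reg in c("beta_extended", "alpha_R", "alpha_L")) {
    poly <- polys[[reg]]
    if (is.null(poly)) next
    inside <- mgcv::in.out(poly, pts)
    out[out == "other" & inside] <- reg
  }
  out[is.na(phi) | is.na(psi)] <- NA_character_
  out
}
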