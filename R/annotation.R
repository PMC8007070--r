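#' Phosphotyrosine detection
#'
#' Finds the unique phosphotyrosine on a chain. A residue qualifies if it is
#' deposited under the standard phospho-Tyr component name (`PTR`), or if it
#' is a `TYR` carrying a phosphorus atom bonded to the ring-hydroxyl oxygen
#' (covalent P-O distance below 1.9 Angstrom in the first frame). The second
#' rule covers models that phosphorylate a tyrosine in place without renaming
#' the residue.
#'
#' @param model a `complex_model`
#' @param chain chain to search (default the peptide chain)
#' @return a [residue_ref()] for the phosphotyrosine
#' @export
detect_phosphotyrosine <- function(model, chain = model$peptide_chain) {
  a <- model$atoms
  if (!chain %in% a$chain)
    stop(sprintf("chain '%s' not present", chain), call. = FALSE)
  res <- unique(a[a$chain == chain, c("chain", "resno", "insert", "resid")])
  hits <- list()
  x1 <- frame_coords(model, 1L)
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    if (r$resid == "PTR") {
      hits[[length(hits) + 1L]] <- r
      next
    }
    if (r$resid == "TYR") {
      idx <- atom_indices(model, chain = chain, resno = r$resno,
                          insert = r$insert)
      nm <- a$elety[idx]
      p_at <- idx[a$elesy[idx] == "P" | nm == "P"]
      oh <- idx[nm == "OH"]
      if (length(p_at) >= 1L && length(oh) == 1L) {
        d <- sqrt(sum((x1[p_at[1L], ] - x1[oh, ])^2))
        if (d < 1.9) hits[[length(hits) + 1L]] <- r
      }
    }
  }
  if (length(hits) == 0L)
    stop(sprintf("no phosphotyrosine found on chain '%s'", chain),
         call. = FALSE)
  if (length(hits) > 1L)
    stop(sprintf(paste("multiple phosphotyrosines on chain '%s' (residues %s);",
                       "annotate the pY explicitly"),
                 chain, paste(vapply(hits, function(h) h$resno, 1), collapse = ", ")),
         call. = FALSE)
  h <- hits[[1L]]
  residue_ref(h$chain, h$resno, h$resid, h$insert)
}

#' pY-relative peptide numbering
#'
#' Assigns the signed offsets ..., -2, -1, 0, +1, ... to the peptide residues,
#' with the phosphotyrosine at 0, N-terminal residues negative and C-terminal
#' residues positive. Offsets follow chain order, so they stay consecutive
#' even across gaps in the author numbering (a gap is reported via `message`).
#'
#' @param model a `complex_model`
#' @param py the phosphotyrosine [residue_ref()] (default auto-detected)
#' @return a `peptide_annotation`: a data frame of peptide residues with an
#'   `offset` column, carrying the pY reference as attribute `py`
#' @export
assign_peptide_numbering <- function(model, py = detect_phosphotyrosine(model)) {
  a <- model$atoms
  ch <- py$chain
  res <- unique(a[a$chain == ch, c("chain", "resno", "insert", "resid")])
  rownames(res) <- NULL
  pos <- which(res$resno == py$resno & res$insert == py$insert)
  if (length(pos) != 1L)
    stop(sprintf("pY residue %s%d not found on chain '%s'",
                 py$resid, py$resno, ch), call. = FALSE)
  res$offset <- seq_len(nrow(res)) - pos
  gaps <- diff(res$resno) != 1L
  if (any(gaps))
    message(sprintf("chain '%s' has %d numbering gap(s); offsets follow chain order",
                    ch, sum(gaps)))
  structure(res, class = c("peptide_annotation", "data.frame"), py = py)
}

#' @noRd
#' Peptide residue at a given pY-relative offset, or NULL.
.residue_at_offset <- function(pep, offset) {
  i <- which(pep$offset == offset)
  if (length(i) != 1L) return(NULL)
  residue_ref(pep$chain[i], pep$resno[i], pep$resid[i], pep$insert[i])
}

# SHP2 N-SH2 defaults: secondary-structure label -> author residue number.
.SH2_DEFAULT_MAP <- c(
  "αA2" = 13L, "αA3" = 14L,
  "βB5" = 32L, "βB7" = 34L,
  "BC1" = 35L, "BC2" = 36L,
  "βC1" = 40L, "βC3" = 42L,
  "βD2" = 51L, "βD3" = 52L, "βD4" = 53L, "βD5" = 54L,
  "βD6" = 55L, "βD′1" = 57L,
  "βE4" = 65L, "EF3" = 68L,
  "αB9" = 81L,
  "BG2" = 86L, "BG3" = 87L, "BG4" = 88L, "BG5" = 89L, "BG6" = 90L,
  "BG7" = 91L, "BG8" = 92L, "BG12" = 96L)

# Accept ASCII spellings of the structural labels.
.normalize_sh2_label <- function(x) {
  x <- gsub("beta", "β", x, fixed = TRUE)
  x <- gsub("alpha", "α", x, fixed = TRUE)
  x <- gsub("'", "′", x, fixed = TRUE)
  x
}

#' SH2 secondary-structure annotation
#'
#' Builds the map from SH2 structural nomenclature (strand/helix/loop labels
#' such as `"βB5"`, `"BC1"`, `"BG7"`) to author residue numbers, with the
#' SHP2 N-SH2 defaults, plus the loop ranges and probe atoms used by the loop
#' and sheet metrics: BC loop 34-38 with pocket probe T42 (βC3), EF loop
#' 66-69 vs BG loop 84-96, and the central-sheet probe pair D40 C (βC1)
#' to Q57 N (βD'1). Every mapped residue must exist on the domain chain.
#'
#' @param model a `complex_model`
#' @param overrides named list/vector overriding label residue numbers, or the
#'   special names `loop_bc`, `loop_ef`, `loop_bg` (integer vectors)
#' @return an `sh2_annotation`
#' @export
build_sh2_annotation <- function(model, overrides = NULL) {
  map <- .SH2_DEFAULT_MAP
  loops <- list(loop_bc = 34:38, loop_ef = 66:69, loop_bg = 84:96)
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (nm %in% names(loops)) {
        loops[[nm]] <- as.integer(overrides[[nm]])
      } else {
        map[.normalize_sh2_label(nm)] <- as.integer(overrides[[nm]])
      }
    }
  }
  dom <- model$atoms[model$atoms$chain == model$domain_chain, ]
  present <- unique(dom$resno)
  missing <- names(map)[!map %in% present]
  if (length(missing) > 0L)
    stop(sprintf("annotation labels map to residues absent from chain '%s': %s",
                 model$domain_chain,
                 paste(sprintf("%s->%d", missing, map[missing]), collapse = ", ")),
         call. = FALSE)
  structure(
    c(list(map = map, chain = model$domain_chain),
      loops,
      list(sheet_probe = list(a = list(resno = map[["βC1"]], elety = "C"),
                              b = list(resno = map[["βD′1"]], elety = "N")),
           pocket_probe = map[["βC3"]])),
    class = "sh2_annotation")
}

#' Resolve an SH2 structural label to a residue
#'
#' @param model a `complex_model`
#' @param dom an `sh2_annotation`
#' @param label structural label, e.g. `"BG7"` or `"betaB5"`
#' @return a [residue_ref()]
#' @export
sh2_residue <- function(model, dom, label) {
  label <- .normalize_sh2_label(label)
  if (!label %in% names(dom$map))
    stop(sprintf("unknown SH2 label '%s'", label), call. = FALSE)
  rn <- dom$map[[label]]
  a <- model$atoms
  i <- which(a$chain == dom$chain & a$resno == rn)[1L]
  residue_ref(dom$chain, rn, a$resid[i], a$insert[i])
}

#' @noRd
#' Reverse lookup: structural label for a domain residue number, or "".
.sh2_label_of <- function(dom, resno) {
  hit <- names(dom$map)[dom$map == resno]
  if (length(hit) >= 1L) hit[[1L]] else ""
}
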