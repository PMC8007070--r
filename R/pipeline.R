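#' Run configuration
#'
#' Validated configuration for a full analysis run. The input is one of
#' * `list(type = "structure", path =, format =)` - a single crystal
#'   structure;
#' * `list(type = "ensemble", topology =, trajectory =, window =)` - a
#'   multi-model PDB or DCD ensemble;
#' * `list(type = "synthetic", spec = <synthetic_ensemble_spec>)` - a
#'   generated ensemble.
#'
#' The configuration is written back verbatim into the output directory for
#' provenance; timestamps live in the run log only, so machine-readable
#' outputs are byte-identical across reruns.
#'
#' @param input input description (see above)
#' @param domain_chain,peptide_chain chain identifiers
#' @param py_resno optional explicit pY residue number (default auto-detect)
#' @param overrides nomenclature overrides for [build_sh2_annotation()]
#' @param criteria an [interaction_criteria()]
#' @param metrics character subset of
#'   `c("contacts", "rmsf", "order", "rama", "sas", "loops", "representative")`
#' @param sas_stride frame stride for the solvent-exposure metric (surface
#'   area is the most expensive per-frame quantity and burial is slowly
#'   varying, so long ensembles are routinely subsampled for it)
#' @param output_dir output directory (created if missing)
#' @param seed integer seed recorded in the bundle
#' @return a `run_config`
#' @export
run_config <- function(input, domain_chain, peptide_chain, py_resno = NULL,
                       overrides = NULL, criteria = interaction_criteria(),
                       metrics = c("contacts", "rmsf", "order", "rama",
                                   "sas", "loops", "representative"),
                       sas_stride = 1L,
                       output_dir = tempfile("sh2pep_run_"), seed = 1L) {
  stopifnot(is.list(input), !is.null(input$type))
  if (!input$type %in% c("structure", "ensemble", "synthetic"))
    stop(sprintf("unknown input type '%s'", input$type), call. = FALSE)
  if (input$type == "structure" && is.null(input$path))
    stop("structure input needs a 'path'", call. = FALSE)
  if (input$type == "ensemble" && is.null(input$topology))
    stop("ensemble input needs a 'topology'", call. = FALSE)
  if (input$type == "synthetic" &&
      !inherits(input$spec, "synthetic_ensemble_spec"))
    stop("synthetic input needs a 'spec'", call. = FALSE)
  bad <- setdiff(metrics, c("contacts", "rmsf", "order", "rama", "sas",
                            "loops", "representative"))
  if (length(bad) > 0L)
    stop(sprintf("unknown metrics: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  stopifnot(sas_stride >= 1L)
  structure(list(input = input, domain_chain = domain_chain,
                 peptide_chain = peptide_chain, py_resno = py_resno,
                 overrides = overrides, criteria = criteria,
                 metrics = metrics, sas_stride = as.integer(sas_stride),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
             con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Loads or generates the input model, builds the peptide and domain
#' annotations, and emits the interaction catalogs (backbone, pY pocket,
#' side chain), the conformation tables (per-residue RMSF, chi1 order
#' parameters, phi/psi with region labels, side-chain exposure), the
#' loop-metric series and summaries, a representative-structure PDB, and a
#' machine-readable JSON bundle plus a run log. Single-structure inputs get
#' distance columns, ensembles persistence columns. Fixed inputs and seed
#' give byte-identical machine-readable outputs.
#'
#' @param config a [run_config()]
#' @return the report bundle (named list), invisibly; all files are written
#'   under `config$output_dir`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)

  truth <- NULL
  model <- switch(config$input$type,
    structure = load_structure(config$input$path,
                               config$input$format %||% "auto",
                               config$domain_chain, config$peptide_chain),
    ensemble = load_ensemble(config$input$topology, config$input$trajectory,
                             config$input$window, config$domain_chain,
                             config$peptide_chain),
    synthetic = {
      s <- sample_ensemble(config$input$spec)
      truth <- s$truth
      s$model
    })
  single <- n_frames(model) == 1L
  .log_line(log_con, "input: %s (%d frames, %d atoms)", model$source,
            n_frames(model), n_atoms(model))
  .log_line(log_con,
            "criteria: hbond <= %.2f A, salt bridge <= %.2f A, stable >= %.0f%%, report >= %.0f%%",
            config$criteria$hbond_max_dist, config$criteria$saltbridge_max_dist,
            100 * config$criteria$persistence_stable_min,
            100 * config$criteria$report_min)

  py <- if (is.null(config$py_resno)) detect_phosphotyrosine(model)
        else {
          a <- model$atoms
          i <- which(a$chain == config$peptide_chain &
                       a$resno == config$py_resno)[1L]
          residue_ref(config$peptide_chain, config$py_resno, a$resid[i],
                      a$insert[i])
        }
  pep <- assign_peptide_numbering(model, py)
  dom <- build_sh2_annotation(model, config$overrides)
  .log_line(log_con, "pY at %s %d; peptide offsets %+d..%+d",
            py$chain, py$resno, min(pep$offset), max(pep$offset))

  bundle <- list(
    package = "sh2pep",
    seed = config$seed,
    input = config$input[setdiff(names(config$input), "spec")],
    source = model$source,
    n_frames = n_frames(model),
    single_frame = single,
    criteria = unclass(config$criteria),
    peptide = as.data.frame(pep))

  if ("contacts" %in% config$metrics) {
    for (mode in c("backbone", "pY_pocket", "sidechain")) {
      pairs <- enumerate_candidate_pairs(model, pep, dom, mode)
      recs <- lapply(pairs, function(p)
        tryCatch(detect_interaction(model, p, config$criteria),
                 error = function(e) NULL))
      recs <- Filter(Negate(is.null), recs)
      tab <- build_interaction_table(recs, config$criteria)
      key <- c(backbone = "backbone_contacts", pY_pocket = "pocket_contacts",
               sidechain = "sidechain_contacts")[[mode]]
      .write_tsv(cbind(model = "run", tab),
                 file.path(config$output_dir, paste0(key, ".tsv")))
      bundle[[key]] <- list(
        cells = as.list(tab[1L, , drop = TRUE]),
        stable = as.list(attr(tab, "stable")[1L, ]),
        occupancy = stats::setNames(
          lapply(recs, function(r)
            if (single) r$distance_series[1L] else r$occupancy),
          vapply(recs, function(r) r$pair$label, "")))
      .log_line(log_con, "%s: %d candidate pairs, %d stable", key,
                length(recs), sum(vapply(recs, function(r) r$stable, TRUE)))
    }
  }

  if ("rmsf" %in% config$metrics && !single) {
    pr <- residue_rmsf(model)
    dr <- residue_rmsf(model, target = model$domain_chain,
                       aggregation = "backbone_atoms")
    .write_tsv(pr, file.path(config$output_dir, "peptide_rmsf.tsv"))
    .write_tsv(dr, file.path(config$output_dir, "domain_rmsf.tsv"))
    bundle$peptide_rmsf <- as.data.frame(pr)
    bundle$domain_rmsf <- as.data.frame(dr)
  }

  if ("order" %in% config$metrics) {
    op <- chi1_profile(model, model$peptide_chain)
    op$cell <- ifelse(op$defined, sprintf("%.2f", op$theta), "x")
    .write_tsv(op, file.path(config$output_dir, "order_parameters.tsv"))
    bundle$order_parameters <- op
  }

  if ("rama" %in% config$metrics) {
    refs <- lapply(seq_len(nrow(pep)), function(i)
      residue_ref(pep$chain[i], pep$resno[i], pep$resid[i], pep$insert[i]))
    rama <- backbone_dihedrals(model, refs)
    .write_tsv(rama, file.path(config$output_dir, "ramachandran.tsv"))
    bundle$ramachandran_regions <- if (nrow(rama) > 0L)
      as.list(tapply(rama$region, rama$resno,
                     function(x) names(sort(table(x), decreasing = TRUE))[1L]))
    else list()
  }

  if ("sas" %in% config$metrics) {
    sas_model <- if (config$sas_stride > 1L && !single)
      subset_frames(model, seq(1L, n_frames(model), by = config$sas_stride))
    else model
    expo <- sidechain_exposure(sas_model)
    .write_tsv(expo, file.path(config$output_dir, "exposure.tsv"))
    bundle$exposure <- as.data.frame(expo)
  }

  if ("loops" %in% config$metrics) {
    lm <- loop_metrics(model, dom)
    .write_tsv(data.frame(frame = seq_along(lm$bc_t42_avg),
                          bc_t42_avg = lm$bc_t42_avg,
                          ef_bg_min = lm$ef_bg_min,
                          sheet_cd = lm$sheet_cd),
               file.path(config$output_dir, "loop_metrics.tsv"))
    .write_tsv(lm$summary, file.path(config$output_dir,
                                     "loop_metrics_summary.tsv"))
    bundle$loop_metrics <- lm$summary
  }

  if ("representative" %in% config$metrics) {
    rep_frame <- representative_structure(model)
    write_complex_pdb(model, file.path(config$output_dir, "representative.pdb"),
                      frames = rep_frame)
    bundle$representative_frame <- rep_frame
    .log_line(log_con, "representative frame: %d", rep_frame)
  }

  if (!is.null(truth)) {
    bundle$ground_truth <- list(
      contact_occupancy = truth$contact_occupancy,
      noise_sigma = truth$spec$noise_sigma)
  }

  # provenance: the config as given, minus unserializable payloads
  cfg_out <- config
  cfg_out$criteria <- unclass(cfg_out$criteria)
  if (config$input$type == "synthetic")
    cfg_out$input <- list(type = "synthetic",
                          seed = config$input$spec$seed,
                          n_frames = config$input$spec$n_frames)
  yaml::write_yaml(unclass(cfg_out),
                   file.path(config$output_dir, "config.yaml"))
  jsonlite::write_json(bundle, file.path(config$output_dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  .log_line(log_con, "bundle written to %s", config$output_dir)
  invisible(bundle)
}

#' Merge report bundles across runs
#'
#' Stacks interaction-table rows of several runs into one table per catalog
#' (outer join on pair labels, `n.a.` where a run lacks a pair; a warning is
#' raised when label sets are disjoint) and collects the per-run loop-metric
#' mean and standard deviation.
#'
#' @param bundles named list of bundles from [run_pipeline()]
#' @return list with one merged data frame per contact catalog and a
#'   `loop_metrics` data frame (run, metric, mean, sd)
#' @export
compare_runs <- function(bundles) {
  stopifnot(length(bundles) >= 2L)
  if (is.null(names(bundles)))
    names(bundles) <- paste0("run", seq_along(bundles))
  out <- list()
  for (key in c("backbone_contacts", "pocket_contacts", "sidechain_contacts")) {
    per_run <- lapply(bundles, function(b) b[[key]]$cells)
    labels <- unique(unlist(lapply(per_run, names)))
    if (length(labels) == 0L) next
    shared <- Reduce(intersect, lapply(per_run, names))
    if (length(shared) == 0L)
      warning(sprintf("%s: no pair label shared across runs (outer join)", key),
              call. = FALSE)
    tab <- do.call(rbind, lapply(per_run, function(cells) {
      row <- stats::setNames(rep("n.a.", length(labels)), labels)
      row[names(cells)] <- unlist(cells)
      as.data.frame(as.list(row), check.names = FALSE,
                    stringsAsFactors = FALSE)
    }))
    rownames(tab) <- names(bundles)
    out[[key]] <- tab
  }
  lm <- do.call(rbind, lapply(names(bundles), function(nm) {
    s <- bundles[[nm]]$loop_metrics
    if (is.null(s)) return(NULL)
    cbind(run = nm, s)
  }))
  out$loop_metrics <- lm
  out
}
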