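# Pipeline driver: mutate -> score -> trajectory metrics -> flexibility
# comparison, with a YAML-configurable entry point and a reproducible
# output bundle (TSV series, JSON summaries, run log).

#' Build a run configuration
#'
#' @param input path to the wild-type PDB, or `NULL` with
#'   `synthetic = TRUE` to run on the toy generator.
#' @param synthetic generate the structure and trajectories with the
#'   synthetic module instead of reading files.
#' @param mutations character vector of mutation strings (`"A:120:Y>F"`).
#' @param trajectories named list of multi-model PDB paths per protein
#'   (names `wt` and the mutation strings); optional, required for
#'   trajectory metrics when not synthetic.
#' @param params_path optional TSV of hydropathic atom constants (default
#'   table used otherwise).
#' @param metrics which trajectory metrics to compute; subset of
#'   `c("rmsd", "rmsf", "rg", "sasa", "dist", "pca")`.
#' @param pairs_path TSV with helix/barrel C-alpha pairs (columns
#'   helix_chain, helix_seq, barrel_chain, barrel_seq); required when
#'   `"dist"` is requested and the run is not synthetic.
#' @param delta_rmsf_threshold flag threshold for RMSF differences,
#'   Angstrom.
#' @param high_flex_threshold wild-type high-flexibility level, Angstrom.
#' @param tail_fraction fraction of final frames used for tail averages.
#' @param epitopes `"default"`, `NULL`, or a path to a TSV with `chain`,
#'   `res_seq`, `epitope`.
#' @param n_frames frames for the synthetic generators.
#' @param seed integer seed for all randomness in the run.
#' @param out_dir output directory.
#' @param log_level `"info"`, `"warn"` or `"quiet"`.
#' @return object of class `run_config`
#' @export
run_config <- function(input = NULL, synthetic = is.null(input),
                       mutations = character(0), trajectories = NULL,
                       params_path = NULL,
                       metrics = c("rmsd", "rmsf", "rg", "sasa", "dist",
                                   "pca"),
                       pairs_path = NULL, delta_rmsf_threshold = 0.7,
                       high_flex_threshold = 2.5, tail_fraction = 0.4,
                       epitopes = "default", n_frames = 100, seed = 1,
                       out_dir = "hintmd_run", log_level = "info") {
  cfg <- list(input = input, synthetic = isTRUE(synthetic),
              mutations = mutations, trajectories = trajectories,
              params_path = params_path, metrics = metrics,
              pairs_path = pairs_path,
              delta_rmsf_threshold = delta_rmsf_threshold,
              high_flex_threshold = high_flex_threshold,
              tail_fraction = tail_fraction, epitopes = epitopes,
              n_frames = as.integer(n_frames), seed = as.integer(seed),
              out_dir = out_dir, log_level = log_level)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file with the fields of [run_config()]
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

validate_run_config <- function(cfg) {
  if (cfg$delta_rmsf_threshold <= 0 || cfg$high_flex_threshold <= 0)
    stop("config error: thresholds must be > 0")
  if (cfg$tail_fraction <= 0 || cfg$tail_fraction > 1)
    stop("config error: tail_fraction must be in (0, 1]")
  bad <- setdiff(cfg$metrics, c("rmsd", "rmsf", "rg", "sasa", "dist", "pca"))
  if (length(bad))
    stop("config error: unknown metric(s): ", paste(bad, collapse = ", "))
  if (!cfg$synthetic) {
    if (is.null(cfg$input) || !file.exists(cfg$input))
      stop("config error: input structure not found: ", cfg$input)
    if ("dist" %in% cfg$metrics && is.null(cfg$pairs_path))
      stop("config error: metric 'dist' requested but no pairs_path given")
  }
  for (m in cfg$mutations) parse_mutation(m)   # syntax check up front
  invisible(cfg)
}

pipeline_log <- function(cfg, level, ...) {
  levels <- c(quiet = 0, warn = 1, info = 2)
  if (levels[[cfg$log_level]] >= levels[[level]])
    message("[", format(Sys.time(), "%H:%M:%S"), "] ", ...)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' For the wild type and each mutant: applies the mutation, computes the
#' hydropathic score table, the requested trajectory metrics, the
#' wild-type-vs-mutant RMSF differences with epitope annotation, and writes
#' a bundle of TSV/JSON outputs plus a run log (config hash, seed).
#' Outputs are deterministic for a fixed configuration.
#'
#' @param cfg a [run_config()] or path to a YAML config file.
#' @return (invisibly) named list of output file paths per protein.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- if (is.null(cfg$params_path)) hint_params() else
    hint_params(read_hint_table(cfg$params_path))
  set.seed(cfg$seed)

  if (cfg$synthetic) {
    wt_model <- make_toy_protein(toy_spec(seed = cfg$seed))
    toy <- attr(wt_model, "toy")
    pairs <- toy$pair
  } else {
    wt_model <- read_pdb(cfg$input)
    pairs <- if (!is.null(cfg$pairs_path))
      utils::read.table(cfg$pairs_path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE) else NULL
  }
  epi <- if (identical(cfg$epitopes, "default")) default_epitopes(
    chain = wt_model$atoms$chain[1]) else if (is.null(cfg$epitopes)) NULL
    else utils::read.table(cfg$epitopes, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)

  proteins <- c(list(wt = wt_model),
                stats::setNames(lapply(cfg$mutations, function(m)
                  apply_mutation(wt_model, m)), cfg$mutations))

  get_traj <- function(tag, model, k) {
    if (cfg$synthetic) {
      # helix breathing plus residue-level harmonic noise, seeded per protein
      ms <- motion_spec(sigma = 0.15, n_frames = cfg$n_frames,
                        seed = cfg$seed + k)
      attr(model, "toy") <- attr(wt_model, "toy")
      br <- make_breathing_trajectory(model, ms)
      hn <- make_harmonic_trajectory(model, ms)
      md_trajectory(model, br$xyz + hn$xyz -
                      matrix(as.numeric(t(coords(model))),
                             nrow(br$xyz), ncol(br$xyz), byrow = TRUE),
                    dt = 1)
    } else if (!is.null(cfg$trajectories[[tag]])) {
      read_multimodel_trajectory(cfg$trajectories[[tag]])
    } else NULL
  }

  out <- list()
  profiles <- list()
  for (k in seq_along(proteins)) {
    tag <- names(proteins)[k]
    model <- proteins[[k]]
    safe <- gsub("[^A-Za-z0-9]", "_", tag)
    pdir <- file.path(cfg$out_dir, safe)
    dir.create(pdir, showWarnings = FALSE)
    files <- character(0)
    pipeline_log(cfg, "info", "processing ", tag)

    files["structure"] <- write_pdb(model, file.path(pdir, "structure.pdb"))
    tab <- tryCatch(hint_total(model, params), error = function(e)
      stop("stage 'hydropathy' failed for ", tag, ": ",
           conditionMessage(e)))
    files["scores"] <- write_tsv(tab$per_residue,
                                 file.path(pdir, "residue_scores.tsv"))
    files["records"] <- write_tsv(
      tab$records[order(-abs(tab$records$b)),
                  c("atom_i", "atom_j", "r", "b", "klass")],
      file.path(pdir, "interaction_records.tsv"))

    traj <- get_traj(tag, model, k)
    summ <- list(schema_version = 1L, protein = tag, seed = cfg$seed,
                 total_B = tab$total_B, components = as.list(tab$components))
    if (!is.null(traj)) {
      nf <- n_frames(traj)
      tail_idx <- seq.int(max(1L, nf - ceiling(cfg$tail_fraction * nf) + 1L),
                          nf)
      if ("rmsd" %in% cfg$metrics)
        files["rmsd"] <- write_tsv(data.frame(
          frame = seq_len(nf), rmsd = rmsd_series(traj)),
          file.path(pdir, "rmsd.tsv"))
      if ("rmsf" %in% cfg$metrics) {
        prof <- rmsf_profile(traj)
        profiles[[tag]] <- prof
        files["rmsf"] <- write_tsv(as.data.frame(prof),
                                   file.path(pdir, "rmsf.tsv"))
      }
      if ("rg" %in% cfg$metrics) {
        rg <- gyration_series(traj)
        files["rg"] <- write_tsv(data.frame(frame = seq_len(nf), rg = rg),
                                 file.path(pdir, "rg.tsv"))
        summ$rg_tail_mean <- mean(rg[tail_idx])
        summ$rg_tail_sd <- stats::sd(rg[tail_idx])
      }
      if ("sasa" %in% cfg$metrics) {
        sa <- sasa_series(traj, params = params)
        files["sasa"] <- write_tsv(data.frame(frame = seq_len(nf),
                                              sasa = sa),
                                   file.path(pdir, "sasa.tsv"))
        summ$sasa_tail_mean <- mean(sa[tail_idx])
      }
      if ("dist" %in% cfg$metrics && !is.null(pairs)) {
        hb <- helix_barrel_distance(traj, pairs)
        files["dist"] <- write_tsv(data.frame(frame = seq_len(nf),
                                              d = hb$d),
                                   file.path(pdir, "helix_barrel.tsv"))
        summ$D_max <- hb$D_max
        summ$D_ave <- hb$D_ave
        summ$D_sd <- hb$D_sd
      }
      if ("pca" %in% cfg$metrics) {
        pc <- pca_essential(traj)
        files["pca"] <- write_tsv(data.frame(frame = seq_len(nf),
                                             PC1 = pc$projections[, 1],
                                             PC2 = pc$projections[, 2]),
                                  file.path(pdir, "pca_projections.tsv"))
        summ$pc_ranges <- as.list(as.data.frame(pc$ranges))
        summ$pc1_explained <- pc$explained[1]
      }
    }
    if (tag != "wt" && !is.null(profiles[[tag]]) &&
        !is.null(profiles[["wt"]])) {
      deltas <- delta_rmsf(profiles[["wt"]], profiles[[tag]],
                           threshold = cfg$delta_rmsf_threshold,
                           high_flex = cfg$high_flex_threshold)
      if (!is.null(epi))
        deltas <- suppressWarnings(annotate_epitopes(deltas, epi))
      files["deltas"] <- write_tsv(as.data.frame(deltas),
                                   file.path(pdir, "delta_rmsf.tsv"))
      flagged <- deltas[deltas$flag != "unchanged" &
                          deltas$epitope != "none", , drop = FALSE]
      summ$flagged_epitope_residues <- if (nrow(flagged))
        I(paste0(flagged$res_name, flagged$res_seq, " (", flagged$epitope,
                 " ", flagged$flag, ")")) else I(character(0))
    }
    sp <- file.path(pdir, "summary.json")
    jsonlite::write_json(summ, sp, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    files["summary"] <- sp
    out[[tag]] <- files
  }
  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  writeLines(c(paste("config_md5:", as.character(tools::md5sum(cfg_path))),
               paste("seed:", cfg$seed),
               paste("proteins:", paste(names(proteins), collapse = " "))),
             file.path(cfg$out_dir, "run_log.txt"))
  invisible(out)
}
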