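# Workflow orchestration: deduplicate decoy sets, rank conformations,
# estimate entropy profiles and entropy differences, with file reports.

#' Pipeline configuration
#'
#' Defaults are the study conditions: T = 300 K, negligibility threshold
#' epsilon = 1e-7, 5 Angstrom cluster separation, 30 histogram bins with
#' Miller-Madow correction.
#'
#' @param temperature Kelvin, > 0.
#' @param epsilon minimal-subset threshold in (0, 1).
#' @param cluster_threshold UPGMA separation criterion (Angstrom), > 0.
#' @param bins histogram bins for the entropy estimators.
#' @param correction `"miller_madow"` or `"none"`.
#' @param rg_coeff unfolded-structure flag: a model is dropped as
#'   unfolded when Rg > rg_coeff * Nres^0.38 (heuristic; folded proteins
#'   follow Rg ~ 2.2 N^0.38 Angstrom).
#' @param seed integer seed for the representative draws.
#' @param outdir output directory, or `NULL` to skip file output.
#' @return A list of class `run_config`.
#' @export
run_config <- function(temperature = 300, epsilon = 1e-7,
                       cluster_threshold = 5, bins = 30,
                       correction = "miller_madow", rg_coeff = 3.3,
                       seed = 1L, outdir = NULL) {
  stopifnot(temperature > 0, epsilon > 0, epsilon < 1,
            cluster_threshold > 0, bins >= 2)
  structure(
    list(temperature = temperature, epsilon = epsilon,
         cluster_threshold = cluster_threshold, bins = bins,
         correction = correction, rg_coeff = rg_coeff,
         seed = as.integer(seed), outdir = outdir),
    class = "run_config"
  )
}

.ensure_outdir <- function(config) {
  if (is.null(config$outdir)) return(NULL)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  config$outdir
}

.write_run_log <- function(config, step, extra = list()) {
  od <- .ensure_outdir(config)
  if (is.null(od)) return(invisible(NULL))
  log <- c(list(
    step = step,
    package_version = as.character(utils::packageVersion("confent")),
    config = config[setdiff(names(config), "outdir")]
  ), extra)
  jsonlite::write_json(log, file.path(od, paste0(step, "_log.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' Deduplicate a decoy set
#'
#' Mirrors the standard decoy-processing protocol: drop models whose
#' sequence differs from the reference, drop models with incomplete
#' residues, flag unfolded models by radius of gyration, then collapse
#' groups of mutually similar models (CA RMSD below the cluster
#' threshold) to one randomly chosen representative via UPGMA.
#'
#' @param x paths to PDB files, or a list/`structure_ensemble` of
#'   `structure_model` objects (named).
#' @param config a [run_config()].
#' @param ref_sequence reference one-letter sequence; defaults to the
#'   most common sequence among the inputs.
#' @param skip_bad if `TRUE`, unreadable files are logged and skipped
#'   instead of raising an error.
#' @return List: `result` (a `cluster_result`), `counts` (input /
#'   dropped at each stage / representatives), `dropped` (named reasons).
#' @export
run_dedup <- function(x, config = run_config(), ref_sequence = NULL,
                      skip_bad = FALSE) {
  dropped <- character(0)
  if (is.character(x)) {
    models <- list()
    for (p in x) {
      m <- tryCatch(read_pdb(p, policy = "first"), error = function(e) e)
      if (inherits(m, "error")) {
        if (!skip_bad) stop("unreadable structure ", p, ": ",
                            conditionMessage(m))
        dropped[basename(p)] <- paste("unreadable:", conditionMessage(m))
        next
      }
      models[[basename(p)]] <- m
    }
  } else {
    models <- as.list(x)
    if (is.null(names(models))) {
      names(models) <- paste0("model", seq_along(models))
    }
  }
  n_input <- length(models) + length(dropped)
  if (length(models) == 0) stop("no readable structures")

  seqs <- vapply(models, function(m) m$sequence, character(1))
  if (is.null(ref_sequence)) {
    ref_sequence <- names(sort(table(seqs), decreasing = TRUE))[1]
  }
  bad_seq <- seqs != ref_sequence
  for (nm in names(models)[bad_seq]) dropped[nm] <- "wrong sequence"
  models <- models[!bad_seq]

  incomplete <- vapply(models, function(m) any(m$residues$incomplete),
                       logical(1))
  for (nm in names(models)[incomplete]) dropped[nm] <- "incomplete residues"
  models <- models[!incomplete]

  unfolded <- vapply(models, function(m) {
    radius_of_gyration(m) > config$rg_coeff * n_residues(m)^0.38
  }, logical(1))
  for (nm in names(models)[unfolded]) dropped[nm] <- "unfolded (Rg flag)"
  models <- models[!unfolded]
  if (length(models) == 0) stop("all structures dropped before clustering")

  if (length(models) == 1) {
    result <- structure(
      list(clusters = list(cluster1 = names(models)),
           representatives = names(models),
           threshold = config$cluster_threshold, seed = config$seed),
      class = "cluster_result"
    )
  } else {
    D <- rmsd_matrix(models, select = "CA")
    result <- upgma_dedup(D, threshold = config$cluster_threshold,
                          seed = config$seed)
  }
  counts <- list(
    input = n_input,
    dropped_unreadable = sum(grepl("^unreadable", dropped)),
    dropped_wrong_sequence = sum(dropped == "wrong sequence"),
    dropped_incomplete = sum(dropped == "incomplete residues"),
    dropped_unfolded = sum(dropped == "unfolded (Rg flag)"),
    clustered = length(models),
    representatives = length(result$representatives)
  )
  od <- .ensure_outdir(config)
  if (!is.null(od)) {
    jsonlite::write_json(
      list(clusters = result$clusters,
           representatives = result$representatives,
           threshold = result$threshold, seed = result$seed),
      file.path(od, "clusters.json"), auto_unbox = TRUE, digits = NA
    )
    .write_run_log(config, "dedup",
                   list(counts = counts, dropped = as.list(dropped)))
  }
  list(result = result, counts = counts, dropped = dropped)
}

#' Rank conformations from an energy table
#'
#' Produces the full ranking report, Boltzmann weights under each cost
#' function, the minimal contributing subset, and the free-energy gap
#' between the two best conformations under the full cost function, in
#' kcal/mol and in multiples of kB T.
#'
#' @param table an `energy_table`, data.frame, or path to a CSV/TSV.
#' @param config a [run_config()].
#' @return List: `report` (a `rank_report`), `weights` (named list of
#'   `weight_vector`), `subset` (a `minimal_subset`), `gaps`.
#' @export
run_rank <- function(table, config = run_config()) {
  table <- energy_table(table)
  T <- config$temperature
  report <- rank_report(table, T = T)
  costs <- c("Eintra", "G0", "Ghat")
  weights <- lapply(costs, function(X) {
    boltzmann_weights(evaluate_cost(table, X), T = T, cost_name = X)
  })
  names(weights) <- costs
  subset <- minimal_subset(table, costs, eps = config$epsilon, T = T)
  ghat <- sort(evaluate_cost(table, "Ghat"))
  gap <- if (length(ghat) > 1) unname(ghat[2] - ghat[1]) else NA_real_
  gaps <- list(Ghat_gap_kcal_mol = gap,
               Ghat_gap_kBT = energy_gap_in_kBT(gap, T = T))
  od <- .ensure_outdir(config)
  if (!is.null(od)) {
    utils::write.table(as.data.frame(report),
                       file.path(od, "rank_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(weights = lapply(weights, function(w) as.list(w$weights)),
           minimal_subset = list(per_cost = subset$per_cost,
                                 joint = subset$joint,
                                 eps = subset$eps),
           gaps = gaps),
      file.path(od, "weights.json"), auto_unbox = TRUE, digits = NA
    )
    .write_run_log(config, "rank", list(n_conformations = nrow(table)))
  }
  list(report = report, weights = weights, subset = subset, gaps = gaps)
}

# read a torsion-sample TSV (header = labels, rows = frames, radians)
.read_torsion_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  torsion_ensemble(as.matrix(tab))
}

#' Estimate an entropy profile from an ensemble
#'
#' @param x a `torsion_ensemble`, a multi-model PDB path, a torsion TSV
#'   path (header = torsion labels, one row per frame, radians), or a
#'   `structure_ensemble`.
#' @param config a [run_config()].
#' @param bfactor_pdb optional path: writes the first model with
#'   per-residue S_i in the B-factor column (PDB input only).
#' @return The `entropy_profile`.
#' @export
run_entropy <- function(x, config = run_config(), bfactor_pdb = NULL) {
  models <- NULL
  if (is.character(x) && length(x) == 1) {
    first <- readLines(x, n = 1)
    if (grepl("^(ATOM|MODEL|HEADER|REMARK|EXPDTA|TITLE)", first)) {
      models <- read_pdb(x, policy = "all")
      ens <- compute_torsions(models)
    } else {
      ens <- .read_torsion_tsv(x)
    }
  } else if (inherits(x, "torsion_ensemble")) {
    ens <- x
  } else {
    models <- x
    ens <- compute_torsions(models)
  }
  if (nrow(ens$samples) < 2) {
    stop("entropy estimation requires an ensemble of at least 2 frames; ",
         "got ", nrow(ens$samples))
  }
  profile <- partial_entropies(ens, bins = config$bins,
                               correction = config$correction)
  od <- .ensure_outdir(config)
  if (!is.null(od)) {
    utils::write.table(as.data.frame(profile),
                       file.path(od, "entropy_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_run_log(config, "entropy",
                   list(total_kB = profile$total,
                        frames = profile$meta$frames))
  }
  if (!is.null(bfactor_pdb) && !is.null(models)) {
    write_pdb(models[[1]], bfactor_pdb, bfactor = as.numeric(profile$Si))
  }
  profile
}

#' Per-residue entropy difference between two profiles, with segments
#'
#' @param A,B `entropy_profile` objects over the same sequence.
#' @param segments optional list of `c(from, to)` residue ranges whose
#'   delta-S sums and fractions of the total are reported.
#' @param config a [run_config()].
#' @param bfactor_pdb optional path and `model` pair
#'   (`list(path =, model =)`): writes `model` with delta S_i as
#'   B-factors for structure coloring.
#' @return List: `difference` (an `entropy_difference`), `segments`
#'   (per-range sum in kB and fraction of the total).
#' @export
run_diff <- function(A, B, segments = NULL, config = run_config(),
                     bfactor_pdb = NULL) {
  d <- entropy_difference(A, B)
  seg <- NULL
  if (!is.null(segments)) {
    seg <- lapply(segments, function(rg) {
      s <- segment_sum(d, rg[1], rg[2])
      list(from = rg[1], to = rg[2], sum_kB = s$sum,
           fraction = s$fraction)
    })
  }
  od <- .ensure_outdir(config)
  if (!is.null(od)) {
    utils::write.table(
      data.frame(resno = as.integer(names(d$deltaSi)),
                 deltaSi_kB = as.numeric(d$deltaSi)),
      file.path(od, "entropy_difference.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    .write_run_log(config, "diff",
                   list(total_kB = d$total, segments = seg))
  }
  if (!is.null(bfactor_pdb)) {
    write_pdb(bfactor_pdb$model, bfactor_pdb$path,
              bfactor = as.numeric(d$deltaSi))
  }
  list(difference = d, segments = seg)
}
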