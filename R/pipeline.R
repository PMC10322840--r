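# Pipeline orchestration: run the stages with a validated configuration and
# write reproducible reports.

.CONFIG_DEFAULTS <- list(
  fasta = NULL,            # input FASTA of ungapped protein sequences
  msa = NULL,              # aligned-FASTA MSA (required for tree/diverge/transpose)
  msa_format = "fasta",
  reference_id = NULL,     # acceptor / divergence reference id
  donor_ids = NULL,        # comma-separated donor ids (default: classified KSR3)
  out_dir = NULL,
  bootstrap_replicates = 1000L,
  seed = 1L,
  correction = "p",
  conservation = 0.8,
  window_pad = 10L,
  min_anchor_score = 200,
  exemplar_threshold = 100,
  gap_open = 11,
  gap_extend = 1,
  verbose = FALSE
)

#' Build a validated run configuration
#'
#' Defaults are documented in the package; unknown keys are rejected.
#'
#' @param ... Configuration values overriding the defaults (see
#'   `ksrtools:::.CONFIG_DEFAULTS` for the key set: `fasta`, `msa`,
#'   `msa_format`, `reference_id`, `donor_ids`, `out_dir`,
#'   `bootstrap_replicates`, `seed`, `correction`, `conservation`,
#'   `window_pad`, `min_anchor_score`, `exemplar_threshold`, `gap_open`,
#'   `gap_extend`, `verbose`).
#' @param file Optional flat `key = value` configuration file parsed before
#'   `...` overrides.
#' @return A `run_config` list.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- .CONFIG_DEFAULTS
  vals <- list(...)
  if (!is.null(file)) {
    lines <- readLines(file, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    parsed <- stats::setNames(
      lapply(kv, function(x) trimws(paste(x[-1], collapse = "="))),
      vapply(kv, function(x) trimws(x[1]), character(1))
    )
    vals <- utils::modifyList(parsed, vals)
  }
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(vals)) {
    v <- vals[[k]]
    if (is.character(v) && k %in% c("bootstrap_replicates", "seed",
                                    "window_pad")) v <- as.integer(v)
    if (is.character(v) && k %in% c("conservation", "min_anchor_score",
                                    "exemplar_threshold", "gap_open",
                                    "gap_extend")) v <- as.numeric(v)
    if (is.character(v) && k == "verbose") v <- as.logical(v)
    cfg[[k]] <- v
  }
  structure(cfg, class = "run_config")
}

.log <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message(...)
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(cfg[order(names(cfg))], file = f)
  unname(tools::md5sum(f))
}

#' Annotate every sequence of a FASTA file
#'
#' Reads `cfg$fasta`, annotates each sequence and writes per-sequence TSV
#' and JSON reports plus a combined `annotations.tsv` into `cfg$out_dir`.
#'
#' @param cfg A [run_config()] with at least `fasta` and `out_dir` set.
#' @return Invisibly, the named list of annotations.
#' @export
run_annotate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$fasta) || is.null(cfg$out_dir)) {
    stop("configuration error: 'fasta' and 'out_dir' are required")
  }
  records <- read_fasta(cfg$fasta)
  if (length(records) == 0) stop("no sequences in ", cfg$fasta)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  anns <- lapply(records, function(rec) {
    .log(cfg, "annotating ", rec$id)
    annotate_kinase(rec, window_pad = cfg$window_pad,
                    min_anchor_score = cfg$min_anchor_score,
                    exemplar_threshold = cfg$exemplar_threshold)
  })
  tabs <- lapply(anns, function(a) {
    write_annotation(a,
                     tsv = file.path(cfg$out_dir, paste0(a$id, ".motifs.tsv")),
                     json = file.path(cfg$out_dir, paste0(a$id, ".annotation.json")))
  })
  utils::write.table(do.call(rbind, tabs),
                     file.path(cfg$out_dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(anns)
}

#' Run the full comparative pipeline
#'
#' annotate -> classify -> tree (bootstrap NJ on the supplied MSA) ->
#' divergence profile against the reference -> mutation transposition onto
#' the reference.  All stage outputs land in `cfg$out_dir` along with a run
#' manifest (inputs, configuration hash, seed, package version, stages
#' completed).
#'
#' @param cfg A [run_config()]; requires `fasta` (or `msa` alone, in which
#'   case ungapped MSA rows are annotated), `msa`, `reference_id`,
#'   `out_dir`.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$out_dir)) stop("configuration error: 'out_dir' is required")
  if (is.null(cfg$msa)) stop("configuration error: 'msa' is required")
  if (is.null(cfg$reference_id)) {
    stop("configuration error: 'reference_id' is required")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  run_stage <- function(name, expr) {
    .log(cfg, "stage: ", name)
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  msa <- run_stage("ingest", {
    m <- read_msa(cfg$msa, cfg$msa_format)
    if (!cfg$reference_id %in% m$ids) {
      stop("reference id '", cfg$reference_id, "' not in MSA")
    }
    m
  })
  records <- if (!is.null(cfg$fasta)) {
    read_fasta(cfg$fasta)
  } else {
    stats::setNames(lapply(msa$ids, function(i) msa_row_record(msa, i)), msa$ids)
  }

  anns <- run_stage("annotate", {
    lapply(records, function(rec) {
      annotate_kinase(rec, window_pad = cfg$window_pad,
                      min_anchor_score = cfg$min_anchor_score,
                      exemplar_threshold = cfg$exemplar_threshold)
    })
  })
  calls <- run_stage("classify", {
    calls <- lapply(anns, classify_family)
    tab <- data.frame(
      id = vapply(calls, function(x) x$id, character(1)),
      label = vapply(calls, function(x) x$label, character(1)),
      confidence = vapply(calls, function(x) x$confidence, character(1)),
      rules = vapply(calls, function(x) paste(x$rules, collapse = "; "),
                     character(1)),
      stringsAsFactors = FALSE)
    utils::write.table(tab, file.path(cfg$out_dir, "family_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls
  })
  tree <- run_stage("tree", {
    tr <- bootstrap_tree(msa, replicates = cfg$bootstrap_replicates,
                         seed = cfg$seed, correction = cfg$correction)
    write_tree_newick(tr, file.path(cfg$out_dir, "nj_bootstrap.nwk"))
    tr
  })
  donors <- if (!is.null(cfg$donor_ids)) {
    strsplit(cfg$donor_ids, ",", fixed = TRUE)[[1]]
  } else {
    ids <- vapply(calls, function(x) x$id, character(1))
    ids[vapply(calls, function(x) x$label, character(1)) == "KSR3"]
  }
  # divergence and transposition work in the coordinates of the reference's
  # MSA row (identical to the record's when the MSA is full length)
  ref_rec <- msa_row_record(msa, cfg$reference_id)
  ref_ann <- annotate_kinase(ref_rec, window_pad = cfg$window_pad,
                             min_anchor_score = cfg$min_anchor_score,
                             exemplar_threshold = cfg$exemplar_threshold)
  profile <- run_stage("diverge", {
    p <- divergence_profile(msa, cfg$reference_id,
                            setdiff(donors, cfg$reference_id))
    write_profile_tsv(p, file.path(cfg$out_dir, "divergence_profile.tsv"))
    rs <- region_summary(p, ref_ann)
    utils::write.table(rs, file.path(cfg$out_dir, "region_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    p
  })
  candidates <- run_stage("transpose", {
    hits <- donor_specific_residues(msa, setdiff(donors, cfg$reference_id),
                                    cfg$reference_id, cfg$conservation)
    cand <- transpose_mutations(hits, ref_rec, ref_ann)
    write_candidates_tsv(cand, file.path(cfg$out_dir, "candidate_mutations.tsv"))
    cand
  })

  manifest <- list(
    package = "ksrtools",
    version = as.character(utils::packageVersion("ksrtools")),
    inputs = list(fasta = cfg$fasta, msa = cfg$msa),
    reference_id = cfg$reference_id,
    donors = donors,
    seed = cfg$seed,
    bootstrap_replicates = cfg$bootstrap_replicates,
    config_hash = .config_hash(unclass(cfg)[setdiff(names(cfg), "out_dir")]),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(annotations = anns, calls = calls, tree = tree,
                 profile = profile, candidates = candidates,
                 manifest = manifest))
}
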