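# Derive a per-family RNG substream seed from the global seed and the
# family id, so adding or reordering families never perturbs the others.
family_seed <- function(seed, family_id) {
  h <- 0
  for (code in utf8ToInt(family_id)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

build_node_profile <- function(aln, cfg, model_id, family_id, node, hmm_dir) {
  if (cfg$engine == "hmmer") {
    build_hmmer_profile(aln, cfg, model_id = model_id, family_id = family_id,
                        hmm_dir = hmm_dir,
                        mean_identity = node$mean_identity, size = node$size)
  } else {
    build_profile(aln, cfg, model_id = model_id, family_id = family_id,
                  mean_identity = node$mean_identity, size = node$size)
  }
}

#' Build the ensemble of profile HMMs for one family
#'
#' Decomposes the family's guide tree recursively at centroid edges (see
#' [decompose]) and builds one profile HMM per subset node on that node's
#' induced alignment.  The root model, built on the full seed alignment,
#' is always present; a family with at most `hard_floor` sequences yields
#' an ensemble of exactly one model.
#'
#' @param fam A [family_record].
#' @param params A [decomposition_params].
#' @param cfg A [backend_config].
#' @param hmm_dir Directory for external-engine model files.
#' @return An object of class `hmm_ensemble`.
#' @export
build_ensemble <- function(fam, params = decomposition_params(),
                           cfg = backend_config(), hmm_dir = tempdir()) {
  stopifnot(inherits(fam, "family_record"))
  res <- tryCatch({
    dec <- decompose(fam$seed, fam$guide_tree, params)
    models <- lapply(dec$nodes, function(node) {
      sub <- induced_alignment(fam$seed, node$taxa)
      build_node_profile(sub, cfg,
                         model_id = sprintf("%s.m%d", fam$family_id, node$id),
                         family_id = fam$family_id, node = node,
                         hmm_dir = file.path(hmm_dir, fam$family_id))
    })
    structure(list(family_id = fam$family_id, threshold = fam$threshold,
                   models = models, decomposition = dec, params = params),
              class = "hmm_ensemble")
  }, error = function(e) {
    stop("family ", fam$family_id, ": ", conditionMessage(e), call. = FALSE)
  })
  res
}

#' @export
print.hmm_ensemble <- function(x, ...) {
  cat(sprintf("hmm_ensemble %s: %d profile HMMs (threshold %.1f bits)\n",
              x$family_id, length(x$models), x$threshold))
  invisible(x)
}

cfg_fingerprint <- function(params, backend, single_hmm) {
  paste(params$max_size_pct, params$min_identity_pct, params$hard_floor,
        backend$engine, backend$gap_threshold, backend$alpha,
        paste(signif(backend$background, 10), collapse = ","),
        single_hmm, sep = "|")
}

#' Build an ensemble-of-HMMs database from a family database
#'
#' The main fitting entry point: for every family, obtain a guide tree
#' (supplied or estimated), decompose it, and build one profile HMM per
#' subset.  With `single_hmm = TRUE` the decomposition degenerates to the
#' root alone (equivalent to `max_size_pct = 100, min_identity_pct = 0`),
#' reproducing the classical one-HMM-per-family baseline.
#'
#' @param db A [family_db].
#' @param params A [decomposition_params].
#' @param backend A [backend_config].
#' @param seed Integer seed; each family uses an independent substream
#'   derived from it.
#' @param single_hmm Build only the root profile per family.
#' @param hmm_dir Directory for external-engine model files.
#' @param skip_errors If `TRUE`, families that fail to build are recorded
#'   in `$failed` and skipped instead of aborting.
#' @return An object of class `ensemble_db`.
#' @export
ensemble_db <- function(db, params = decomposition_params(),
                        backend = backend_config(), seed = 1L,
                        single_hmm = FALSE, hmm_dir = tempdir(),
                        skip_errors = FALSE) {
  stopifnot(inherits(db, "family_db"))
  if (single_hmm)
    params <- decomposition_params(max_size_pct = 100, min_identity_pct = 0,
                                   hard_floor = params$hard_floor)
  ensembles <- list()
  failed <- character()
  for (fid in names(db)) {
    old <- .Random.seed_save()
    set.seed(family_seed(seed, fid))
    ens <- tryCatch(build_ensemble(db[[fid]], params, backend, hmm_dir),
                    error = function(e) e)
    .Random.seed_restore(old)
    if (inherits(ens, "error")) {
      if (!skip_errors) stop(ens)
      failed <- c(failed, fid)
      warning("skipping family ", fid, ": ", conditionMessage(ens), call. = FALSE)
    } else {
      ensembles[[fid]] <- ens
    }
  }
  if (length(ensembles) == 0L) stop("no ensembles could be built", call. = FALSE)
  structure(list(ensembles = ensembles, params = params, backend = backend,
                 seed = as.integer(seed), single_hmm = single_hmm,
                 failed = failed,
                 fingerprint = cfg_fingerprint(params, backend, single_hmm)),
            class = "ensemble_db")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.ensemble_db <- function(x, ...) {
  p <- vapply(x$ensembles, function(e) length(e$models), integer(1))
  cat(sprintf("ensemble_db: %d families, %d profile HMMs (%s engine%s)\n",
              length(x$ensembles), sum(p), x$backend$engine,
              if (x$single_hmm) ", single-HMM mode" else ""))
  invisible(x)
}

#' @export
summary.ensemble_db <- function(object, ...) {
  rows <- lapply(object$ensembles, function(e) {
    root <- e$decomposition$nodes[[1L]]
    data.frame(family_id = e$family_id, n_sequences = root$size,
               mean_identity = root$mean_identity,
               n_models = length(e$models), threshold = e$threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("summary.ensemble_db", "data.frame"))
}

#' @export
print.summary.ensemble_db <- function(x, ...) {
  cat("ensemble_db summary:\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

serialize_model <- function(model, dir) {
  if (inherits(model, "ref_profile_hmm")) {
    list(engine = "reference", model_id = model$model_id,
         family_id = model$family_id, subset_ids = model$subset_ids,
         M = model$M, match_cols = model$match_cols,
         e_match = model$e_match, background = unname(model$background),
         trans = model$trans, size = model$size,
         mean_identity = model$mean_identity)
  } else {
    fname <- paste0(gsub("[^A-Za-z0-9._-]", "_", model$model_id), ".hmm")
    file.copy(model$hmm_path, file.path(dir, fname), overwrite = TRUE)
    list(engine = "hmmer", model_id = model$model_id,
         family_id = model$family_id, subset_ids = model$subset_ids,
         hmm_file = fname, size = model$size,
         mean_identity = model$mean_identity)
  }
}

deserialize_model <- function(obj, dir) {
  if (identical(obj$engine, "reference")) {
    e_match <- matrix(unlist(obj$e_match), ncol = 20L, byrow = TRUE,
                      dimnames = list(NULL, AA_ALPHABET))
    structure(list(model_id = obj$model_id, family_id = obj$family_id,
                   subset_ids = unlist(obj$subset_ids), M = obj$M,
                   match_cols = unlist(obj$match_cols), e_match = e_match,
                   background = stats::setNames(unlist(obj$background), AA_ALPHABET),
                   trans = lapply(obj$trans, unlist),
                   size = obj$size, mean_identity = obj$mean_identity),
              class = c("ref_profile_hmm", "profile_hmm"))
  } else {
    path <- file.path(dir, obj$hmm_file)
    if (!file.exists(path))
      stop("missing model file for ", obj$model_id, ": ", path, call. = FALSE)
    structure(list(model_id = obj$model_id, family_id = obj$family_id,
                   subset_ids = unlist(obj$subset_ids), hmm_path = path,
                   size = obj$size, mean_identity = obj$mean_identity),
              class = c("hmmer_profile_hmm", "profile_hmm"))
  }
}

#' Save an ensemble database to a directory
#'
#' Layout: `config.json` at the top level plus one directory per family
#' containing `ensemble.json` (decomposition and model parameters) and,
#' for the external engine, the `.hmm` files.
#'
#' @param x An [ensemble_db].
#' @param dir Output directory (created if needed).
#' @export
save_ensemble_db <- function(x, dir) {
  stopifnot(inherits(x, "ensemble_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(params = unclass(x$params),
              backend = unclass(x$backend)[c("engine", "gap_threshold", "alpha",
                                             "background", "hmmer_evalue",
                                             "hmmer_extra")],
              seed = x$seed, single_hmm = x$single_hmm,
              fingerprint = x$fingerprint,
              families = names(x$ensembles))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  for (fid in names(x$ensembles)) {
    e <- x$ensembles[[fid]]
    fdir <- file.path(dir, gsub("[^A-Za-z0-9._-]", "_", fid))
    dir.create(fdir, showWarnings = FALSE)
    nodes <- lapply(e$decomposition$nodes, function(nd)
      nd[c("id", "parent", "children", "depth", "taxa", "size", "mean_identity")])
    payload <- list(family_id = e$family_id, threshold = e$threshold,
                    n = e$decomposition$n,
                    params = unclass(e$params), nodes = nodes,
                    models = lapply(e$models, serialize_model, dir = fdir))
    jsonlite::write_json(payload, file.path(fdir, "ensemble.json"),
                         auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  }
  invisible(dir)
}

#' Load an ensemble database saved by [save_ensemble_db]
#'
#' @param dir Directory written by [save_ensemble_db].
#' @return An [ensemble_db].
#' @export
load_ensemble_db <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path))
    stop("not an ensemble database directory (no config.json): ", dir,
         call. = FALSE)
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  params <- decomposition_params(cfg$params$max_size_pct,
                                 cfg$params$min_identity_pct,
                                 cfg$params$hard_floor)
  backend <- backend_config(engine = cfg$backend$engine,
                            gap_threshold = cfg$backend$gap_threshold,
                            alpha = cfg$backend$alpha,
                            background = unlist(cfg$backend$background),
                            hmmer_evalue = cfg$backend$hmmer_evalue,
                            hmmer_extra = unlist(cfg$backend$hmmer_extra))
  fp <- cfg_fingerprint(params, backend, isTRUE(cfg$single_hmm))
  if (!identical(fp, cfg$fingerprint))
    warning("config fingerprint mismatch: database built under a different ",
            "configuration than its config.json reports", call. = FALSE)
  ensembles <- list()
  for (fid in cfg$families) {
    fdir <- file.path(dir, gsub("[^A-Za-z0-9._-]", "_", fid))
    ej <- file.path(fdir, "ensemble.json")
    if (!file.exists(ej))
      stop("missing ensemble.json for family ", fid, call. = FALSE)
    obj <- jsonlite::read_json(ej, simplifyVector = FALSE)
    nodes <- lapply(obj$nodes, function(nd) {
      list(id = nd$id, parent = if (is.null(nd$parent)) NA_integer_ else nd$parent,
           children = if (length(nd$children)) unlist(nd$children) else NULL,
           depth = nd$depth, taxa = unlist(nd$taxa), size = nd$size,
           mean_identity = nd$mean_identity)
    })
    dec <- structure(list(nodes = nodes, n = obj$n, params = params, tree = NULL),
                     class = "hmm_decomposition")
    models <- lapply(obj$models, deserialize_model, dir = fdir)
    ensembles[[fid]] <- structure(
      list(family_id = obj$family_id, threshold = obj$threshold,
           models = models, decomposition = dec, params = params),
      class = "hmm_ensemble")
  }
  structure(list(ensembles = ensembles, params = params, backend = backend,
                 seed = as.integer(cfg$seed), single_hmm = isTRUE(cfg$single_hmm),
                 failed = character(), fingerprint = cfg$fingerprint),
            class = "ensemble_db")
}
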