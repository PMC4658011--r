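#' Run the radiomic pipeline end to end
#'
#' Executes the configured stages — simulate, segment, kinetics, features,
#' classify, cluster — and writes their outputs plus a run manifest to
#' `out_dir`. Any stage can be skipped by supplying its product: a config
#' with a `table` entry starts directly from a feature CSV in the standard
#' lesion-table layout, skipping the imaging stages.
#'
#' Config entries (JSON file or R list):
#' \describe{
#'   \item{`phantom`}{arguments for [phantom_spec()]; the phantom is
#'     generated, segmented ([segment_breast()], [region_grow_tumor()],
#'     [fuzzy_cmeans_partition()]), mapped ([parametric_maps()]) and its
#'     79-feature record written to `lesion_features.csv`.}
#'   \item{`volume`}{path to a 4-D NIfTI to process instead of a phantom;
#'     needs `seed_point` and `intensity_band` for tumor growing, and
#'     optionally `chest_wall` (`list(axis, k, side)`).}
#'   \item{`feature_table`}{arguments for [feature_table_spec()]; a
#'     synthetic labeled table is generated and written to `table.csv`.}
#'   \item{`table`}{path to an existing feature CSV; imaging and simulation
#'     stages are skipped.}
#'   \item{`classify`}{list with `task`, `scopes` (default `"tumor"` and
#'     `"tumor+bpe"`) and [cv_config()] arguments; writes per-scope metric
#'     and selection-frequency TSVs and a paired model comparison.}
#'   \item{`cluster`}{list with `restarts`; writes the BPE cluster
#'     assignment and partition composition.}
#'   \item{`seed`}{integer master seed; stage seeds are derived from it.}
#' }
#'
#' @param config path to a JSON config or an R list.
#' @param out_dir output directory (created).
#' @param seed optional master seed overriding the config's.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("missing input: ", config)
    config_digest <- unname(tools::md5sum(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    config_digest <- digest_object(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(if (!is.null(seed)) seed else
                     if (!is.null(config$seed)) config$seed else 1L)

  manifest <- list(package_version = as.character(utils::packageVersion("radbpe")),
                   config_digest = config_digest, master_seed = seed,
                   stages = list(), inputs = list(), outputs = list())
  log_stage <- function(name, t0, note = NULL) {
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(proc.time()[3] - t0), 3), note = note)
  }
  add_output <- function(path) {
    manifest$outputs[[basename(path)]] <<- unname(tools::md5sum(path))
  }

  tab <- NULL

  if (!is.null(config$table)) {
    if (!file.exists(config$table)) stop("missing input: ", config$table)
    t0 <- proc.time()[3]
    manifest$inputs[[basename(config$table)]] <-
      unname(tools::md5sum(config$table))
    tab <- read_feature_csv(config$table)
    log_stage("read_table", t0,
              "segmentation/kinetics/features skipped: table supplied")
  } else if (!is.null(config$feature_table)) {
    t0 <- proc.time()[3]
    args <- config$feature_table
    args$seed <- seed
    tab <- generate_feature_table(do.call(feature_table_spec, args))
    p <- file.path(out_dir, "table.csv")
    write_feature_csv(tab, p); add_output(p)
    log_stage("simulate_table", t0)
  }

  if (!is.null(config$phantom) || !is.null(config$volume)) {
    t0 <- proc.time()[3]
    if (!is.null(config$phantom)) {
      args <- config$phantom; args$seed <- seed
      ph <- generate_dce_phantom(do.call(phantom_spec, args))
      vol <- ph$volume
    } else {
      if (!file.exists(config$volume)) stop("missing input: ", config$volume)
      manifest$inputs[[basename(config$volume)]] <-
        unname(tools::md5sum(config$volume))
      vol <- read_volume_nifti(config$volume)
      ph <- NULL
    }
    cw <- NULL
    if (!is.null(config$chest_wall))
      cw <- chest_wall_plane(dim(vol$data)[1:3],
                             axis = config$chest_wall$axis,
                             k = config$chest_wall$k,
                             side = config$chest_wall$side %||% "le")
    breast <- segment_breast(vol, chest_wall = cw)
    sp <- if (!is.null(config$seed_point)) as.integer(config$seed_point)
          else round(colMeans(which(ph$masks$tumor, arr.ind = TRUE)))
    band <- if (!is.null(config$intensity_band)) config$intensity_band
            else {
              # default band: everything above the parenchyma/tumor split
              # of a three-class Otsu within the breast
              v3 <- vol_frame(vol, 3)
              c(otsu_threshold(v3[breast], k = 2L)[2], max(v3))
            }
    tumor <- region_grow_tumor(vol, seed_point = sp, intensity_band = band)
    fcm <- fuzzy_cmeans_partition(vol, mask = breast & !tumor, seed = seed)
    masks <- compartment_masks(breast | tumor, tumor & breast,
                               fcm$parenchyma & !tumor)
    maps <- parametric_maps(vol, masks$breast)
    feats <- extract_lesion_features(maps, masks)
    p <- file.path(out_dir, "lesion_features.csv")
    df <- as.data.frame(as.list(feats), check.names = FALSE)
    write.csv(df, p, row.names = FALSE); add_output(p)
    for (nm in names(masks)) {
      mp <- file.path(out_dir, paste0(nm, "_mask.nii.gz"))
      write_mask_nifti(masks[[nm]], mp); add_output(mp)
    }
    log_stage("imaging", t0)
  }

  if (!is.null(config$classify)) {
    if (is.null(tab)) stop("missing input: classify stage needs a table")
    t0 <- proc.time()[3]
    cc <- config$classify
    scopes <- cc$scopes %||% c("tumor", "tumor+bpe")
    task <- cc$task %||% "tn_vs_others"
    cfg_args <- cc[intersect(names(cc), names(formals(cv_config)))]
    cfg_args$seed <- seed
    cfg <- do.call(cv_config, cfg_args)
    sub <- task_filter(tab, task)
    results <- list()
    for (sc in scopes) {
      res <- run_nested_cv(sub, cfg, scope = sc)
      results[[sc]] <- res
      tag <- gsub("[^a-z]+", "_", sc)
      p <- file.path(out_dir, sprintf("metrics_%s.tsv", tag))
      write.table(res$summary, p, sep = "\t", row.names = FALSE,
                  quote = FALSE); add_output(p)
      p <- file.path(out_dir, sprintf("selection_%s.tsv", tag))
      write.table(selection_frequency(res, floor = 50), p, sep = "\t",
                  row.names = FALSE, quote = FALSE); add_output(p)
    }
    if (length(results) == 2L) {
      cmp <- compare_models(results[[1]], results[[2]])
      p <- file.path(out_dir, "model_comparison.tsv")
      write.table(cmp, p, sep = "\t", row.names = FALSE, quote = FALSE)
      add_output(p)
    }
    log_stage("classify", t0, paste("task", task))
  }

  if (!is.null(config$cluster)) {
    if (is.null(tab)) stop("missing input: cluster stage needs a table")
    t0 <- proc.time()[3]
    cl <- cluster_bpe(tab, restarts = config$cluster$restarts %||% 50L,
                      seed = seed)
    p <- file.path(out_dir, "cluster_assignment.csv")
    write.csv(data.frame(case = seq_along(cl$result$assignment),
                         partition = cl$result$assignment),
              p, row.names = FALSE); add_output(p)
    p <- file.path(out_dir, "composition.tsv")
    comp <- cl$composition
    write.table(data.frame(enriched_partition = comp$enriched_partition,
                           tn_in_enriched = comp$tn_in_enriched,
                           tn_total = comp$tn_total,
                           fisher_p = comp$fisher_p),
                p, sep = "\t", row.names = FALSE, quote = FALSE)
    add_output(p)
    log_stage("cluster", t0)
  }

  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 digest of an R object via its canonical JSON serialization
digest_object <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
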