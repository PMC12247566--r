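# tiny FNV-1a string hash for stamping outputs with their configuration
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a cohort container to disk
#'
#' Directory layout: `cohort.json` (network, spec and schema version),
#' `spec.yaml` (human-readable spec sidecar), and one array file per
#' participant/condition block under `blocks/`.
#'
#' @param cohort a `cohort` object.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(file.path(path, "blocks"), recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    schema_version = 1L,
    fs = cohort$spec$fs,
    net = list(n_parcels = cohort$net$n_parcels,
               edges = cohort$net$edges,
               condition_gains = cohort$net$condition_gains,
               power_coupling = cohort$net$power_coupling,
               seed = cohort$net$seed),
    spec = unclass(cohort$spec)
  )
  meta$spec$band <- unclass(meta$spec$band)
  jsonlite::write_json(meta, file.path(path, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(meta$spec, file.path(path, "spec.yaml"))
  for (pt in seq_along(cohort$blocks)) {
    for (cd in names(cohort$blocks[[pt]])) {
      saveRDS(cohort$blocks[[pt]][[cd]],
              file.path(path, "blocks", sprintf("p%03d_%s.rds", pt, cd)))
    }
  }
  invisible(path)
}

#' Read a cohort container from disk
#'
#' @param path directory written by [write_cohort()].
#' @return a `cohort` object with bit-identical arrays.
#' @export
read_cohort <- function(path) {
  meta_path <- file.path(path, "cohort.json")
  if (!file.exists(meta_path)) stopf("not a cohort container: missing %s", meta_path)
  meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                   error = function(e) stopf("unreadable cohort metadata at %s: %s",
                                             meta_path, conditionMessage(e)))
  for (k in c("schema_version", "fs", "net", "spec"))
    if (is.null(meta[[k]])) stopf("schema error: missing '%s' in %s", k, meta_path)
  if (meta$schema_version != 1L) stopf("unsupported schema version %s", meta$schema_version)
  sp <- meta$spec
  spec <- cohort_spec(
    n_participants = sp$n_participants, conditions = sp$conditions,
    epochs_per_condition = sp$epochs_per_condition, fs = sp$fs,
    epoch_len = sp$epoch_len,
    band = band_spec(sp$band$name, sp$band$f_lo, sp$band$f_hi,
                     n_cycles = sp$band$n_cycles, center = sp$band$center),
    participant_sd = sp$participant_sd, noise_exponent = sp$noise_exponent,
    snr = sp$snr, amp_floor = sp$amp_floor, seed = sp$seed)
  net <- make_network(meta$net$n_parcels, meta$net$edges,
                      meta$net$condition_gains, meta$net$power_coupling,
                      meta$net$seed)
  blocks <- lapply(seq_len(spec$n_participants), function(pt) {
    bl <- lapply(spec$conditions, function(cd) {
      f <- file.path(path, "blocks", sprintf("p%03d_%s.rds", pt, cd))
      if (!file.exists(f)) stopf("schema error: missing block file %s", f)
      tryCatch(readRDS(f),
               error = function(e) stopf("I/O error reading %s: %s", f,
                                         conditionMessage(e)))
    })
    names(bl) <- spec$conditions
    bl
  })
  structure(list(blocks = blocks, net = net, spec = spec), class = "cohort")
}

#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown fields are
#' rejected so typos cannot silently change an analysis.
#'
#' @param generator list of arguments for [cohort_spec()] (used when no
#'   `cohort_path` is given).
#' @param network list with `n_parcels`, `edges`, `condition_gains`,
#'   `power_coupling` for [make_network()].
#' @param cohort_path optional path to an existing cohort container.
#' @param bands character vector of band names from [default_bands()].
#' @param n_perm number of label permutations.
#' @param quantile tail mass for the max-delta thresholds, in (0, 1).
#' @param seed master seed.
#' @param hub integer hub parcel indices.
#' @param destinations named list of destination parcel index vectors.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(generator = list(), network = NULL, cohort_path = NULL,
                       bands = "high_alpha", n_perm = 100, quantile = 0.025,
                       seed = 1L, hub = NULL, destinations = NULL,
                       out_dir = tempfile("dpteflow_run_")) {
  if (!(quantile > 0 && quantile < 1)) stopf("quantile must be in (0,1)")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (!all(bands %in% names(default_bands()))) stopf("unknown band name(s)")
  if (is.null(cohort_path) && is.null(network)) stopf("need a network or a cohort_path")
  structure(list(generator = generator, network = network,
                 cohort_path = cohort_path, bands = bands, n_perm = n_perm,
                 quantile = quantile, seed = as.integer(seed), hub = hub,
                 destinations = destinations, out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with [run_config()] fields; unknown keys are
#'   rejected.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, then for each configured band: extracts
#' phase, computes per-epoch dPTE and the connection table, fits the
#' null/simple/full ladder for every connection, calibrates AIC-delta
#' thresholds by within-participant label permutation, classifies the
#' connections, and — when a hub is configured — produces the hub outflow
#' summary, hub-by-destination model, flow-power association fits and the
#' SNR-confound comparison. All tables are written as TSV (with band, seed
#' and config-hash columns) plus JSON scalars and a plain-text log.
#'
#' @param config a [run_config()].
#' @return result bundle (named list, one entry per band), invisibly;
#'   side effect: files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hcfg <- unclass(config)
  hcfg$out_dir <- NULL   # the hash identifies the analysis, not where it lands
  cfg_hash <- fnv1a(jsonlite::toJSON(hcfg, auto_unbox = TRUE, force = TRUE,
                                     digits = NA))
  logf <- file.path(config$out_dir, "run.log")
  logline <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                    file = logf, append = TRUE)
  cat(sprintf("dpteflow run %s seed=%d\n", cfg_hash, config$seed), file = logf)

  stage <- "cohort"
  res <- tryCatch({
    cohort <- if (!is.null(config$cohort_path)) {
      read_cohort(config$cohort_path)
    } else {
      gen <- config$generator
      gen$seed <- gen$seed %||% config$seed
      spec <- do.call(cohort_spec, gen)
      nw <- config$network
      net <- make_network(nw$n_parcels, nw$edges, nw$condition_gains,
                          nw$power_coupling %||% 0, spec$seed)
      generate_cohort(net, spec)
    }
    logline("cohort: %d participants, %d parcels",
            cohort$spec$n_participants, cohort$net$n_parcels)

    out <- list()
    for (bname in config$bands) {
      stage <- paste0("band:", bname)
      band <- default_bands()[[bname]]
      conn <- cohort_connections(cohort, band)
      logline("%s: delay=%d bins=%d", bname, conn$params$delay, conn$params$n_bins)
      fits <- fit_all_ladders(conn$table)
      thr <- permutation_thresholds(conn$table, n_perm = config$n_perm,
                                    quantile = config$quantile,
                                    seed = config$seed)
      cls <- classify_connections(fits, thr)
      stamp <- function(df) cbind(df, band = bname, seed = config$seed,
                                  config_hash = cfg_hash)
      utils::write.table(stamp(cls),
                         file.path(config$out_dir, paste0(bname, "_connections.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(band = bname, thr_simple = thr$thr_simple, thr_full = thr$thr_full,
             n_perm = thr$n_perm, quantile = thr$quantile, seed = config$seed,
             config_hash = cfg_hash, delay = conn$params$delay,
             n_bins = conn$params$n_bins,
             n_nonconverged = sum(!cls$converged)),
        file.path(config$out_dir, paste0(bname, "_thresholds.json")),
        auto_unbox = TRUE, digits = NA)

      band_res <- list(params = conn$params, classification = cls, thresholds = thr)

      if (!is.null(config$hub)) {
        stage <- paste0("association:", bname)
        hs <- hub_summary(conn$table, config$hub, cohort$net$n_parcels)
        band_res$hub <- hs
        utils::write.table(stamp(hs$model),
                           file.path(config$out_dir, paste0(bname, "_hub_model.tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        if (!is.null(config$destinations)) {
          recs <- hub_flow_records(conn$table, config$hub, config$destinations)
          band_res$hub_destination <- hub_destination_model(recs)
          pw <- cohort_band_power(cohort, band)
          fp <- lapply(names(config$destinations), function(dn) {
            didx <- config$destinations[[dn]]
            pdest <- pw[pw$parcel %in% didx, , drop = FALSE]
            pdest <- stats::aggregate(log_power ~ participant + condition + epoch,
                                      pdest, mean)
            flow_power_model(recs, pdest, destination = dn)
          })
          names(fp) <- names(config$destinations)
          band_res$flow_power <- fp
          for (dn in names(fp))
            utils::write.table(stamp(fp[[dn]]$slopes),
                               file.path(config$out_dir,
                                         paste0(bname, "_flow_power_", dn, ".tsv")),
                               sep = "\t", row.names = FALSE, quote = FALSE)
          # hub-level confound check: summed outflow vs mean hub log power
          hubpow <- pw[pw$parcel %in% config$hub, , drop = FALSE]
          hubpow <- stats::aggregate(log_power ~ participant + condition + epoch,
                                     hubpow, mean)
          conf <- merge(hs$flows, hubpow, by = c("participant", "condition", "epoch"))
          band_res$snr_confound <- snr_confound_comparison(conf)
          jsonlite::write_json(band_res$snr_confound[c("aic", "delta_both_vs_power",
                                                       "independent_of_power", "n")],
                               file.path(config$out_dir,
                                         paste0(bname, "_snr_confound.json")),
                               auto_unbox = TRUE, digits = NA)
        }
      }
      out[[bname]] <- band_res
    }
    out
  }, error = function(e) {
    logline("ERROR in stage %s: %s", stage, conditionMessage(e))
    stopf("pipeline failed in stage '%s': %s", stage, conditionMessage(e))
  })
  logline("done")
  invisible(res)
}
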