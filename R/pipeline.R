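#' Run configuration
#'
#' A single global seed fans out to per-stage child seeds via a counter-based
#' derivation (`seed * 1009 + stage_index`, folded into 32-bit range) so that
#' stages can be re-run independently yet reproducibly. Module parameter
#' blocks override the defaults of [fscv_params()], [count_sim_params()],
#' [behavior_sim_params()] and [bootstrap_deg_counts()].
#'
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @param fscv,counts,behavior,bootstrap named lists of overrides for the
#'   corresponding stage parameters.
#' @param format report format, `"json"` or `"tsv"` where applicable.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("stimdyn_demo_"),
                       fscv = list(), counts = list(), behavior = list(),
                       bootstrap = list(), format = c("json", "tsv")) {
  format <- match.arg(format)
  structure(list(seed = as.integer(seed), out_dir = out_dir, fscv = fscv,
                 counts = counts, behavior = behavior, bootstrap = bootstrap,
                 format = format),
            class = "run_config")
}

#' Load a run configuration from JSON
#'
#' Strict schema: unknown top-level keys are rejected.
#'
#' @param path JSON file with any of the [run_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "out_dir", "fscv", "counts", "behavior", "bootstrap",
             "format")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

child_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 1009 + stage_index) %% 2147483647)
}

#' End-to-end demonstration run
#'
#' With one master seed, executes the three analysis arms on synthetic data:
#' (1) FSCV concentration series for an amphetamine-like ladder
#' (0.1-10 uM) and a methylphenidate-like ladder (1-30 uM), with kinetic
#' fitting and Ki recovery; (2) a single-nucleus count simulation followed by
#' projection classification and the balanced-bootstrap core-vs-shell DEG
#' comparison; (3) simulated vigilance sessions scored into a
#' dose-response table. Outputs and a manifest (package version, master and
#' child seeds, stage status) are written under `config$out_dir`; the bundle
#' is byte-identical across runs with the same config.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with elements `potency` (per-drug
#'   [estimate_ki()] results), `deg` (core/shell distributions and the
#'   comparison test), `behavior` (dose-response data.frame) and
#'   `manifest_path`.
#' @export
run_demo <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "stimdyn",
                   version = as.character(utils::packageVersion("stimdyn")),
                   seed = config$seed, stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "completed",
                                     seed = child_seed(config$seed,
                                                       length(manifest$stages) + 1))
    res
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  ## stage 1: FSCV potency recovery
  potency <- stage("fscv_potency", {
    ladders <- list(amph = c(0.1, 0.3, 1, 3, 10), mph = c(1, 3, 10, 30))
    out <- lapply(names(ladders), function(drug) {
      p <- do.call(fscv_params,
                   utils::modifyList(list(da_per_pulse = 1.2, vmax = 2.5,
                                          km = 0.16, ki_true = 2,
                                          seed = child_seed(config$seed, 1)),
                                     config$fscv))
      traces <- simulate_concentration_series(p, ladders[[drug]])
      base_fit <- fit_transient(traces[[1]])
      series <- apparent_km_series(traces[-1], base_fit)
      ki <- estimate_ki(series, baseline_km = base_fit$km)
      utils::write.table(series,
                         file.path(config$out_dir,
                                   paste0("apparent_km_", drug, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(unclass(ki),
                           file.path(config$out_dir,
                                     paste0("potency_", drug, ".json")),
                           auto_unbox = TRUE, digits = NA)
      ki
    })
    names(out) <- names(ladders)
    out
  })

  ## stage 2: balanced-bootstrap DEG comparison
  deg <- stage("deg_bootstrap", {
    csp <- do.call(count_sim_params,
                   utils::modifyList(
                     list(n_nuclei = 60, n_genes = 600, seed = child_seed(config$seed, 2),
                          sex_effect = data.frame(gene = 11:40, lfc = 2,
                                                  projection = "core")),
                     config$counts))
    cm <- simulate_counts(csp)
    filt <- qc_filter(cm, min_genes = 50)  # small demo matrix
    norm <- normalize_log1p(filt)
    proj <- classify_projection(norm)
    bc <- utils::modifyList(list(n_boot = 20, n_per_sex = 30), config$bootstrap)
    dists <- lapply(c(core = "core", shell = "shell"), function(region) {
      idx <- proj == region
      sub <- norm
      sub$values <- norm$values[, idx, drop = FALSE]
      sub$nucleus_meta <- norm$nucleus_meta[idx, , drop = FALSE]
      bootstrap_deg_counts(sub, n_boot = bc$n_boot, n_per_sex = bc$n_per_sex,
                           seed = child_seed(config$seed,
                                             2 + (region == "shell")))
    })
    cmp <- compare_regions(dists$core, dists$shell)
    jsonlite::write_json(list(core_counts = dists$core$counts,
                              shell_counts = dists$shell$counts,
                              u = cmp$statistic, p = cmp$p_value),
                         file.path(config$out_dir, "deg_comparison.json"),
                         digits = NA)
    list(core = dists$core, shell = dists$shell, test = cmp)
  })

  ## stage 3: behavioral dose-response
  behavior <- stage("behavior_dose_response", {
    doses <- c(0, 0.01, 0.03, 0.3, 1, 3)
    # dose-dependent hit probability: mild inverted-U around 1 mg/kg
    dose_hit <- function(d, base = 0.6)
      min(0.95, base + 0.25 * d / (0.5 + d) - 0.05 * (d > 2))
    base_sessions <- lapply(1:3, function(i) {
      bp <- do.call(behavior_sim_params,
                    utils::modifyList(list(seed = child_seed(config$seed, 10 + i)),
                                      config$behavior))
      summarize_session(simulate_session(bp))
    })
    bl <- baseline_performance(base_sessions)
    rows <- lapply(seq_along(doses), function(i) {
      det <- vapply(1:2, function(cycle) {
        bp <- do.call(behavior_sim_params,
                      utils::modifyList(
                        list(hit_prob = dose_hit(doses[i]),
                             seed = child_seed(config$seed,
                                               100 + 10 * i + cycle)),
                        config$behavior))
        s <- summarize_session(simulate_session(bp))
        pc <- percent_change(s, bl)
        c(pc$pct_change_hit_rate, pc$pct_change_dprime)
      }, numeric(2))
      data.frame(dose = doses[i],
                 pct_change_hit_rate = mean(det[1, ]),
                 pct_change_dprime = mean(det[2, ]),
                 n_determinations = 2L)
    })
    dr <- do.call(rbind, rows)
    utils::write.table(dr, file.path(config$out_dir, "dose_response.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    dr
  })

  write_manifest()
  invisible(list(potency = potency, deg = deg, behavior = behavior,
                 manifest_path = file.path(config$out_dir, "manifest.json")))
}

#' Validate input files
#'
#' Format checks for the package's external interchange formats: trace CSVs
#' (plus JSON sidecars), MatrixMarket count triplets and event-log TSVs.
#' Problems are reported, not raised.
#'
#' @param paths character vector of files or MTX directories.
#' @return data.frame: `path`, `kind`, `ok`, `message`.
#' @export
validate_inputs <- function(paths) {
  check_one <- function(path) {
    if (dir.exists(path)) {
      need <- c("matrix.mtx", "genes.tsv", "barcodes.tsv", "metadata.tsv")
      missing <- need[!file.exists(file.path(path, need))]
      if (length(missing))
        return(list(kind = "mtx_dir", ok = FALSE,
                    message = paste("missing:", paste(missing, collapse = ", "))))
      res <- tryCatch({
        cm <- read_counts_mtx(path)
        list(kind = "mtx_dir", ok = TRUE,
             message = sprintf("%d genes x %d nuclei", nrow(cm$counts),
                               ncol(cm$counts)))
      }, error = function(e) list(kind = "mtx_dir", ok = FALSE,
                                  message = conditionMessage(e)))
      return(res)
    }
    if (grepl("\\.csv$", path)) {
      return(tryCatch({
        tr <- read_trace_csv(path)
        list(kind = "trace_csv", ok = TRUE,
             message = sprintf("%d samples, unit %s", length(tr$time), tr$unit))
      }, error = function(e) list(kind = "trace_csv", ok = FALSE,
                                  message = conditionMessage(e))))
    }
    if (grepl("\\.tsv$", path)) {
      return(tryCatch({
        ev <- parse_event_log(path)
        list(kind = "event_log", ok = TRUE,
             message = sprintf("%d events", nrow(ev)))
      }, error = function(e) list(kind = "event_log", ok = FALSE,
                                  message = conditionMessage(e))))
    }
    list(kind = "unknown", ok = FALSE, message = "unrecognised input type")
  }
  rows <- lapply(paths, function(p) {
    r <- check_one(p)
    data.frame(path = p, kind = r$kind, ok = r$ok, message = r$message)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's analysis functions, used by the
#' `inst/cli/stimdyn.R` script. Subcommands: `run-demo`, `simulate-fscv`,
#' `fit-fscv`, `potency`, `simulate-counts`, `classify`, `deg-bootstrap`,
#' `compare-regions`, `simulate-behavior`, `score-behavior`,
#' `dose-response`, `validate`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: stimdyn <subcommand> [--key value ...]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list()
  kv <- args[-1]
  i <- 1
  while (i <= length(kv)) {
    key <- sub("^--", "", kv[i])
    opts[[key]] <- if (i + 1 <= length(kv)) kv[i + 1] else ""
    i <- i + 2
  }
  num <- function(key, default) if (is.null(opts[[key]])) default
                                else as.numeric(opts[[key]])
  str_ <- function(key, default) if (is.null(opts[[key]])) default
                                 else opts[[key]]
  seed <- as.integer(num("seed", 1))

  switch(cmd,
    "run-demo" = {
      cfg <- run_config(seed = seed, out_dir = str_("out", "stimdyn_demo"))
      run_demo(cfg)
      cat("demo written to", cfg$out_dir, "\n")
    },
    "simulate-fscv" = {
      p <- fscv_params(inhibitor_conc = num("conc", 0), seed = seed,
                       noise_sd = num("noise-sd", 0))
      proto <- if (str_("protocol", "tonic") == "tonic") tonic_protocol()
               else phasic_protocol(num("frequency", 20))
      write_trace_csv(simulate_fscv_trace(p, proto,
                                          as_current = num("noise-sd", 0) > 0),
                      str_("out", "trace.csv"))
    },
    "fit-fscv" = {
      tr <- read_trace_csv(str_("trace", stop("--trace required")))
      fit <- fit_transient(tr)
      jsonlite::write_json(unclass(fit), str_("out", "fit.json"),
                           auto_unbox = TRUE, digits = NA)
      print(fit)
    },
    "simulate-counts" = {
      cm <- simulate_counts(count_sim_params(seed = seed))
      write_counts_mtx(cm, str_("out", "counts_mtx"))
    },
    "classify" = {
      cm <- read_counts_mtx(str_("counts", stop("--counts required")))
      proj <- classify_projection(normalize_log1p(qc_filter(cm)))
      print(table(proj))
    },
    "deg-bootstrap" = {
      cm <- read_counts_mtx(str_("counts", stop("--counts required")))
      norm <- normalize_log1p(qc_filter(cm))
      region <- str_("region", "core")
      proj <- classify_projection(norm)
      idx <- proj == region
      norm$values <- norm$values[, idx, drop = FALSE]
      norm$nucleus_meta <- norm$nucleus_meta[idx, , drop = FALSE]
      d <- bootstrap_deg_counts(norm, n_boot = num("n-boot", 50),
                                n_per_sex = num("n-per-sex", 30), seed = seed)
      jsonlite::write_json(d$counts, str_("out", "deg_counts.json"),
                           digits = NA)
    },
    "compare-regions" = {
      a <- unlist(jsonlite::read_json(str_("a", stop("--a required")),
                                      simplifyVector = TRUE))
      b <- unlist(jsonlite::read_json(str_("b", stop("--b required")),
                                      simplifyVector = TRUE))
      r <- compare_regions(a, b)
      cat(sprintf("U = %g, p = %g\n", r$statistic, r$p_value))
    },
    "simulate-behavior" = {
      write_event_log(simulate_session(behavior_sim_params(seed = seed)),
                      str_("out", "session.tsv"))
    },
    "score-behavior" = {
      s <- summarize_session(parse_event_log(str_("log", stop("--log required"))))
      print(s)
    },
    "validate" = {
      print(validate_inputs(kv[!grepl("^--", kv)]))
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
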