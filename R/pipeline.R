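#' Density-shift plot for one OTU (labeled vs control)
#'
#' Normalized relative abundance of an OTU as a function of buoyant
#' density in the labeled (red) and control (blue) gradients, with
#' vertical lines at each distribution's weighted mean and the
#' labeled-minus-control difference (delWM) annotated to 4 decimals.
#'
#' @param labeled,control [gradient_profile()]s.
#' @param otu_id OTU to plot.
#' @param dna_floor DNA floor of [build_distribution()].
#' @return A ggplot object.
#' @export
plot_density_shift <- function(labeled, control, otu_id, dna_floor = 0.1) {
  d13 <- build_distribution(labeled, otu_id, dna_floor)
  d12 <- build_distribution(control, otu_id, dna_floor)
  if (is.null(d13) || is.null(d12))
    stop("OTU '", otu_id, "' absent from one of the gradients")
  df <- rbind(
    data.frame(density = d13$densities, p = d13$weights, gradient = "13C"),
    data.frame(density = d12$densities, p = d12$weights, gradient = "12C")
  )
  wm13 <- weighted_mean_density(d13)
  wm12 <- weighted_mean_density(d12)
  wms <- data.frame(wm = c(wm13, wm12), gradient = c("13C", "12C"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$density, y = .data$p,
                                   colour = .data$gradient)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(data = wms,
                        ggplot2::aes(xintercept = .data$wm,
                                     colour = .data$gradient),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`13C` = "#c0392b",
                                            `12C` = "#2e6da4")) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = sprintf("delWM = %.4f g/ml", wm13 - wm12)) +
    ggplot2::labs(title = otu_id, x = "Buoyant density (g/ml)",
                  y = "Normalized abundance") +
    ggplot2::theme_minimal()
}

#' Digest of a run configuration
#'
#' MD5 of a canonical serialization of the configuration, embedded in
#' every output so that runs with different thresholds are
#' distinguishable.
#'
#' @param config A list.
#' @return Hex digest string.
#' @export
config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  flat <- unlist(config)
  writeLines(paste(names(flat), vapply(flat, format, "",
                                       digits = 15), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full paired-gradient shift pipeline
#'
#' Reads a labeled/control gradient pair, runs [compare_gradients()], and
#' writes into the output directory: `results.tsv` (the per-OTU shift
#' table, with seed, thresholds and config digest in its comment header),
#' `summary.json` (machine-readable counts), `run.log`, and optionally a
#' density-shift plot per significant OTU. Any failure removes the
#' partial outputs it created.
#'
#' @param config Either a list or the path of a YAML file with fields:
#'   `labeled`, `control` (gradient TSV paths), optional `taxonomy`
#'   (two-column TSV otu_id/taxonomy), `out_dir`, optional `analysis`
#'   (overrides of [analysis_config()]), optional `model` (overrides of
#'   [labeling_model()]), `seed`, `plots` (logical, default FALSE).
#' @return Invisibly, a list with `results`, `summary`, and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("labeled", "control"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("config field '", f, "' must name an existing gradient table")
  out_dir <- config$out_dir %||% "tagsip_out"
  seed <- as.integer(config$seed %||% 1L)
  cfg <- do.call(analysis_config, config$analysis %||% list())
  model <- do.call(labeling_model, config$model %||% list())
  digest <- config_digest(list(analysis = unclass(cfg),
                               model = unclass(model), seed = seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  created <- character()
  on_fail <- function(e) { unlink(created); stop(e) }

  tryCatch({
    set.seed(seed)
    labeled <- read_gradient_table(config$labeled, isotope = "13C",
                                   quiet = TRUE)
    control <- read_gradient_table(config$control, isotope = "12C",
                                   quiet = TRUE)
    taxonomy <- NULL
    if (!is.null(config$taxonomy)) {
      tx <- utils::read.table(config$taxonomy, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      taxonomy <- stats::setNames(tx[[2]], tx[[1]])
    }
    results <- compare_gradients(labeled, control, model, cfg, taxonomy)
    header <- c(paste0("seed: ", seed),
                paste0("config_digest: ", digest),
                paste0("shift_threshold: ", cfg$shift_threshold),
                paste0("ks_alpha: ", cfg$ks_alpha),
                paste0("min_total_reads: ", cfg$min_total_reads),
                paste0("top_n: ", cfg$top_n),
                paste0("dna_floor: ", cfg$dna_floor))
    res_path <- file.path(out_dir, "results.tsv")
    created <- c(created, res_path)
    write_results_table(results, res_path, header = header)

    smry <- summary(results)
    smry$config_digest <- digest
    smry$seed <- seed
    sum_path <- file.path(out_dir, "summary.json")
    created <- c(created, sum_path)
    jsonlite::write_json(smry, sum_path, auto_unbox = TRUE, digits = NA)

    log_path <- file.path(out_dir, "run.log")
    created <- c(created, log_path)
    writeLines(c(sprintf("tagsip run %s", format(Sys.time())),
                 sprintf("config_digest: %s", digest),
                 sprintf("seed: %d", seed),
                 sprintf("labeled: %s (%d fractions)", config$labeled,
                         nrow(labeled$fractions)),
                 sprintf("control: %s (%d fractions)", config$control,
                         nrow(control$fractions)),
                 sprintf("model: density(GC) = %.6f + %.6f GC",
                         model$gc_intercept, model$gc_slope),
                 sprintf("thresholds: shift > %g g/ml, KS alpha %g, >= %d reads, top %d",
                         cfg$shift_threshold, cfg$ks_alpha,
                         cfg$min_total_reads, cfg$top_n),
                 sprintf("OTUs analyzed: %d, passed normality: %d, significant: %d",
                         smry$n_analyzed, smry$n_passed_normality,
                         smry$n_significant)),
               log_path)

    plot_paths <- character()
    if (isTRUE(config$plots)) {
      plot_dir <- file.path(out_dir, "plots")
      dir.create(plot_dir, showWarnings = FALSE)
      sig <- results$otu_id[which(results$significant)]
      for (otu in sig) {
        p <- plot_density_shift(labeled, control, otu, cfg$dna_floor) +
          ggplot2::labs(caption = paste0("config ", digest))
        fp <- file.path(plot_dir, paste0(otu, ".png"))
        created <- c(created, fp)
        ggplot2::ggsave(fp, p, width = 5, height = 3.5, dpi = 150)
        plot_paths <- c(plot_paths, fp)
      }
    }
    invisible(list(results = results, summary = smry,
                   paths = list(results = res_path, summary = sum_path,
                                log = log_path, plots = plot_paths)))
  }, error = on_fail)
}
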