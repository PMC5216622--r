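# Orchestration and human-readable outputs: per-species summary table,
# histogram data, Welch test battery and the full pipeline writing result
# CSVs. The test battery mirrors the study design — one unweighted Welch test
# per species plus one weighted community-level test — with no multiplicity
# correction.

#' Per-species summary statistics
#'
#' One row per (species, period): mean, sample SD (n - 1 denominator),
#' SE = SD / sqrt(n), and n.
#'
#' @param observations Observation tibble.
#' @return A tibble `species`, `period`, `mean`, `sd`, `se`, `n`, sorted by
#'   species then period.
#' @export
#' @examples
#' obs <- generate_observations(default_config(), seed = 1)
#' summarize_sizes(obs)
summarize_sizes <- function(observations) {
  out <- dplyr::summarise(
    dplyr::group_by(observations, .data$species, .data$period),
    mean = mean(.data$diameter),
    sd = sd(.data$diameter),
    n = dplyr::n(),
    .groups = "drop"
  )
  if (any(out$n < 2)) {
    bad <- out[out$n < 2, ]
    ps_stop(sprintf("need >= 2 observations per (species, period); (%s, %s) has %d",
                    bad$species[1], bad$period[1], bad$n[1]),
            "paleosize_insufficient_data_error")
  }
  out$se <- out$sd / sqrt(out$n)
  dplyr::arrange(out[, c("species", "period", "mean", "sd", "se", "n")],
                 .data$species, .data$period)
}

#' Histogram bin counts with normal-curve ordinates
#'
#' Bins each (species, period) group into left-closed intervals
#' `[k*bin_width, (k+1)*bin_width)` aligned to multiples of the bin width, so
#' halving the bin width refines the bins exactly. Alongside the counts it
#' returns the ordinate of the fitted normal density at each bin midpoint,
#' scaled to count units (`n * bin_width * dnorm`), for overlay plots that
#' assess normality visually.
#'
#' @param observations Observation tibble.
#' @param bin_width Bin width in μm (default 2).
#' @return A tibble `species`, `period`, `bin_left`, `bin_right`, `count`,
#'   `normal_ordinate`. Counts within a group sum to that group's n.
#' @export
histogram_data <- function(observations, bin_width = 2) {
  stopifnot(bin_width > 0)
  groups <- split(observations,
                  paste(observations$species, observations$period, sep = "\r"))
  pieces <- lapply(groups, function(g) {
    idx <- floor(g$diameter / bin_width)
    bins <- seq(min(idx), max(idx))
    counts <- tabulate(idx - min(idx) + 1L, nbins = length(bins))
    mid <- (bins + 0.5) * bin_width
    m <- mean(g$diameter)
    s <- sd(g$diameter)
    ord <- if (s > 0) nrow(g) * bin_width * dnorm(mid, m, s) else
      ifelse(mid == m, nrow(g), 0)
    tibble::tibble(species = g$species[1], period = g$period[1],
                   bin_left = bins * bin_width,
                   bin_right = (bins + 1) * bin_width,
                   count = counts, normal_ordinate = ord)
  })
  out <- dplyr::bind_rows(pieces)
  dplyr::arrange(out, .data$species, .data$period, .data$bin_left)
}

#' Assemble a pipeline configuration
#'
#' Collects input locations (or in-memory tables), the period contrast and
#' analysis options for [run_pipeline()]. Either provide `obs` and
#' `assemblage` (paths or tibbles), or a `seed` alone to simulate both from
#' [default_config()].
#'
#' @param obs,assemblage,literature Paths to CSV files or tibbles from the
#'   readers. `literature` defaults to the bundled literature table.
#' @param ref_period,cmp_period The period contrast; deltas and test
#'   differences are comparison minus reference.
#' @param out_dir Directory for result CSVs and the run log.
#' @param seed Integer seed; required when simulating, otherwise recorded in
#'   the run log only.
#' @param pooling,correct,df_mode Analysis options, see
#'   [species_pooled_means()], [wtd_sd()], [weighted_welch_test()].
#' @param bin_width Histogram bin width (μm).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(obs = NULL, assemblage = NULL,
                            literature = system.file("extdata", "literature_sizes.csv",
                                                     package = "paleosize"),
                            ref_period = "warm", cmp_period = "cold",
                            out_dir = ".", seed = NULL,
                            pooling = "pooled", correct = TRUE,
                            df_mode = "satterthwaite", bin_width = 2) {
  if (ref_period == cmp_period) {
    ps_stop("reference and comparison periods must differ",
            "paleosize_validation_error")
  }
  if ((is.null(obs) || is.null(assemblage)) && is.null(seed)) {
    ps_stop("provide obs and assemblage tables, or a seed to simulate them",
            "paleosize_validation_error")
  }
  structure(list(obs = obs, assemblage = assemblage, literature = literature,
                 ref_period = ref_period, cmp_period = cmp_period,
                 out_dir = out_dir, seed = seed, pooling = pooling,
                 correct = correct, df_mode = df_mode, bin_width = bin_width),
            class = "pipeline_config")
}

.load_input <- function(x, reader) {
  if (is.character(x)) reader(x) else tibble::as_tibble(x)
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) the observation and assemblage tables, then computes
#' the per-species summary, the community-weighted means at all three levels
#' (with and without intraspecific change, and literature-based), the
#' decomposition of the between-period change, the Welch test battery (one
#' unweighted test per species, one weighted community test), the
#' measured-vs-literature comparison and histogram data, and writes each as a
#' CSV to `config$out_dir` plus a `run_log.txt` recording package version,
#' options, seed and input checksums. Any stage failure aborts with a message
#' naming the stage, and partial outputs are removed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with elements `summary`, `community`,
#'   `decomposition`, `tests`, `literature`, `histogram`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- file.path(out_dir, c("summary.csv", "community.csv", "decomp.csv",
                                  "tests.csv", "litcmp.csv", "histogram.csv",
                                  "run_log.txt"))
  written <- character(0)
  stage <- "load inputs"
  res <- tryCatch({
    if (is.null(config$obs)) {
      cfg <- default_config()
      obs <- generate_observations(cfg, config$seed)
      asm <- generate_assemblage(cfg)
      checksums <- "inputs simulated from default_config()"
    } else {
      obs <- .load_input(config$obs, read_observations)
      asm <- .load_input(config$assemblage, read_assemblage)
      checksums <- if (is.character(config$obs) && is.character(config$assemblage)) {
        paste0(basename(c(config$obs, config$assemblage)), " md5=",
               tools::md5sum(c(config$obs, config$assemblage)))
      } else "inputs passed in memory"
    }
    lit <- .load_input(config$literature, read_literature)

    stage <- "summary"
    summary <- summarize_sizes(obs)

    stage <- "decomposition"
    dec <- decompose_size_change(obs, asm, config$ref_period, config$cmp_period,
                                 pooling = config$pooling, correct = config$correct)
    included <- intersect(unique(obs$species), unique(asm$species))

    stage <- "literature comparison"
    lit <- lit[lit$species %in% included, ]
    missing_lit <- setdiff(included, lit$species)
    if (length(missing_lit) > 0) {
      ps_stop(sprintf("no literature entry for species '%s'", missing_lit[1]),
              "paleosize_missing_species_error")
    }
    lit_rows <- lapply(sort(included), function(sp) {
      d <- obs$diameter[obs$species == sp]
      compare_species(sp, mean(d), range(d), lit[lit$species == sp, ])
    })
    litcmp <- dplyr::bind_rows(lit_rows)
    lit_comm <- dplyr::bind_rows(lapply(c(config$ref_period, config$cmp_period),
      function(p) literature_community_mean(
        lit, species_weights(asm, p, included), config$correct)))
    community <- dplyr::bind_rows(dec$community, lit_comm)

    stage <- "tests"
    test_rows <- lapply(sort(included), function(sp) {
      a <- obs$diameter[obs$species == sp & obs$period == config$ref_period]
      b <- obs$diameter[obs$species == sp & obs$period == config$cmp_period]
      dplyr::bind_cols(tibble::tibble(test = sp, level = "species"), welch_test(a, b))
    })
    w_samples <- lapply(c(config$ref_period, config$cmp_period), function(p) {
      w <- species_weights(asm, p, included)
      o <- observation_weights(obs[obs$period == p & obs$species %in% included, ], w)
      weighted_sample(o$diameter, o$weight)
    })
    comm_test <- dplyr::bind_cols(
      tibble::tibble(test = "community", level = "weighted"),
      weighted_welch_test(w_samples[[1]], w_samples[[2]],
                          df_mode = config$df_mode, correct = config$correct))
    tests <- dplyr::bind_rows(c(test_rows, list(comm_test)))

    stage <- "histogram"
    hist <- histogram_data(obs, config$bin_width)

    stage <- "write outputs"
    w <- function(x, f) { write.csv(x, f, row.names = FALSE, quote = FALSE, na = "")
                          written <<- c(written, f); f }
    w(summary, outputs[1]); w(community, outputs[2])
    w(dec$decomposition, outputs[3]); w(tests, outputs[4])
    w(litcmp, outputs[5]); w(hist, outputs[6])
    log_lines <- c(
      sprintf("paleosize %s", as.character(utils::packageVersion("paleosize"))),
      sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
      sprintf("reference period: %s", config$ref_period),
      sprintf("comparison period: %s", config$cmp_period),
      sprintf("seed: %s", ifelse(is.null(config$seed), "none", config$seed)),
      sprintf("pooling: %s; weighted-SD correction: %s; df mode: %s; bin width: %g",
              config$pooling, config$correct, config$df_mode, config$bin_width),
      checksums)
    writeLines(log_lines, outputs[7]); written <- c(written, outputs[7])
    list(summary = summary, community = community,
         decomposition = dec$decomposition, tests = tests,
         literature = litcmp, histogram = hist)
  }, error = function(e) {
    unlink(written)
    ps_stop(sprintf("pipeline failed at stage '%s': %s", stage,
                    conditionMessage(e)), "paleosize_pipeline_error")
  })
  invisible(res)
}
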