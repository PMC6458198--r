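#' Pipeline configuration
#'
#' Declarative description of one end-to-end run.  Each kinetic branch (one
#' per tracer) must name exactly one input source: a simulation spec
#' (`simulate`), a TAC CSV (`csv`), or an image prefix (`image`, as written
#' by [write_dynamic_image()]).  The calibration branch takes a simulation
#' spec, a CSV, or a fixed conversion factor; the growth branch a simulation
#' spec list or a CSV.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Root seed; every stage derives its own stream from it.
#' @param tracers Named list of kinetic branches, e.g.
#'   `list("FLT-like" = list(simulate = tracer_kinetics_spec()))`.
#' @param growth `list(simulate = <named list of growth_model_spec>)` or
#'   `list(csv = path)`.
#' @param fricke `list(simulate = fricke_series_spec())`, `list(csv = path)`
#'   or `list(C = 0.09)`.
#' @param control_group Control group name for the response stage.
#' @param A0 Reference activity (MBq) override; `NULL` = estimate from the
#'   whole-body curve ([estimate_a0()]) where needed.
#' @param nuclide A [radionuclide()].
#' @param include_tail Extrapolate integrals beyond the measured window.
#' @param tail Tail reading for [auc_to_infinity()].
#' @param posthoc `"dunnett"` or `"tukey"`.
#' @param nsim Monte Carlo draws for Dunnett.
#' @return Validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("theradose_"),
                            seed = 1L,
                            tracers = list(
                              "FLT-like" = list(simulate = tracer_kinetics_spec("FLT-like")),
                              "FDG-like" = list(simulate = tracer_kinetics_spec("FDG-like"))),
                            growth = list(simulate = default_growth_specs()),
                            fricke = list(simulate = fricke_series_spec()),
                            control_group = "Control",
                            A0 = NULL,
                            nuclide = f18(),
                            include_tail = TRUE,
                            tail = "physical",
                            posthoc = "dunnett",
                            nsim = 1e5) {
  check_branch <- function(branch, allowed, label) {
    supplied <- intersect(names(branch), allowed)
    if (length(supplied) != 1L)
      stop("branch '", label, "' must supply exactly one of {",
           paste(allowed, collapse = ", "), "}; got {",
           paste(supplied, collapse = ", "), "}", call. = FALSE)
    supplied
  }
  stopifnot(is.list(tracers), length(tracers) >= 1L, !is.null(names(tracers)))
  for (nm in names(tracers))
    check_branch(tracers[[nm]], c("simulate", "csv", "image"), nm)
  check_branch(growth, c("simulate", "csv"), "growth")
  check_branch(fricke, c("simulate", "csv", "C"), "fricke")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 tracers = tracers, growth = growth, fricke = fricke,
                 control_group = control_group, A0 = A0,
                 nuclide = as_radionuclide(nuclide),
                 include_tail = isTRUE(include_tail),
                 tail = match.arg(tail, c("physical", "literal")),
                 posthoc = match.arg(posthoc, c("dunnett", "tukey")),
                 nsim = nsim),
            class = "pipeline_config")
}

#' Default treatment-group growth specs
#'
#' Control plus three treatment arms whose onset lags give true enhancement
#' factors 1.8, 2.1 and 3.7 relative to control (the effect sizes the
#' response stage is exercised against), n = 4 per group, 10% measurement
#' noise.
#'
#' @param V0 Baseline volume (mm^3).
#' @param g Growth rate (1/day), default doubling time 3 days.
#' @param noise_sigma Lognormal measurement SD.
#' @param n_animals Animals per group.
#' @return Named list of [growth_model_spec()].
#' @export
default_growth_specs <- function(V0 = 150, g = log(2) / 3, noise_sigma = 0.1,
                                 n_animals = 4L) {
  base_5td <- log(5) / g
  efs <- c("Control" = 1, "TRT 15 MBq" = 1.8, "TRT 25 MBq" = 2.1,
           "5FU + TRT 15 MBq" = 3.7)
  specs <- lapply(efs, function(ef) {
    growth_model_spec(V0 = V0, growth_rate = g,
                      lag_days = (ef - 1) * base_5td,
                      noise_sigma = noise_sigma, n_animals = n_animals,
                      follow_up_days = ceiling(3.7 * base_5td) + 7)
  })
  names(specs) <- names(efs)
  specs
}

# resolve one kinetic branch to %IA/g + uncorrected-MBq curves and A0
resolve_tracer_branch <- function(branch, cfg, seed) {
  if (!is.null(branch$simulate)) {
    pct <- simulate_tacs(branch$simulate, nuclide = cfg$nuclide, seed = seed)
    A0 <- cfg$A0 %||% attr(pct, "A0")
  } else if (!is.null(branch$csv)) {
    pct <- read_tac_csv(branch$csv, A0 = cfg$A0 %||% NA_real_)
    A0 <- cfg$A0
  } else {
    loaded <- read_dynamic_image(branch$image)
    mbq_set <- extract_tacs(loaded$image, loaded$masks)
    A0 <- cfg$A0 %||% estimate_a0(mbq_set[["whole body"]])
    pct <- tac_set(lapply(mbq_set, function(tc)
      to_percent_ia_per_gram(tc, A0 = A0)), A0 = A0)
  }
  mbq_unc <- tac_set(lapply(pct, function(tc) {
    if (tc$units == "%IA/g") tc <- to_megabecquerel(tc)
    if (tc$decay_corrected)
      tc <- decay_correct(tc, cfg$nuclide, "to-uncorrected")
    tc
  }), A0 = A0 %||% NA_real_)
  if (is.null(A0)) {
    wb <- pct[["whole body"]]
    if (is.null(wb) || wb$units != "MBq")
      stop("cannot determine A0; supply it in the config", call. = FALSE)
    A0 <- estimate_a0(wb)
  }
  list(pct = pct, mbq_unc = mbq_unc, A0 = A0)
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(out_dir, "FAILED")
    writeLines(sprintf("stage: %s\ncause: %s", name, conditionMessage(e)),
               marker)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and writes the report
#' bundle: per-tracer TACs, residence-time tables, tumor-to-tissue ratio
#' tables, absorbed-dose tables, the tumor-response summary, the group
#' statistics, and a manifest recording the seed and every flag in effect.
#' Re-running with the same config produces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the bundle (list of tables) of class
#'   `theradose_bundle`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(config$out_dir, "FAILED"))
  bundle <- list()
  input_hashes <- character(0)

  branches <- run_stage("quantify", config$out_dir, {
    out <- list()
    for (i in seq_along(config$tracers)) {
      nm <- names(config$tracers)[i]
      br <- config$tracers[[nm]]
      if (!is.null(br$csv) && file.exists(br$csv))
        input_hashes[basename(br$csv)] <- unname(tools::md5sum(br$csv))
      out[[nm]] <- resolve_tracer_branch(br, config,
                                         derive_seed(config$seed, i))
    }
    out
  })
  for (nm in names(branches))
    write_tac_csv(branches[[nm]]$pct,
                  file.path(config$out_dir,
                            paste0("tacs_", gsub("\\W+", "_", nm), ".csv")))

  bundle$residence_time <- run_stage("kinetics", config$out_dir, {
    do.call(rbind, lapply(names(branches), function(nm) {
      b <- branches[[nm]]
      rt <- residence_time_table(b$mbq_unc, A0 = b$A0,
                                 nuclide = config$nuclide,
                                 tail = config$tail,
                                 include_tail = config$include_tail)
      cbind(tracer = nm, rt, stringsAsFactors = FALSE)
    }))
  })

  bundle$ratios <- run_stage("ratios", config$out_dir, {
    tissues <- c("kidneys", "liver", "brain", "heart")
    do.call(rbind, lapply(names(branches), function(nm) {
      pct <- branches[[nm]]$pct
      tumors <- intersect(c("primary tumor", "contralateral tumor"),
                          names(pct))
      tis <- intersect(tissues, names(pct))
      if (length(tumors) == 0L || length(tis) == 0L) return(NULL)
      do.call(rbind, lapply(tumors, function(tu)
        do.call(rbind, lapply(tis, function(ti)
          cbind(tracer = nm, tumor_to_tissue_ratio(pct, tu, ti),
                stringsAsFactors = FALSE)))))
    }))
  })

  calib <- run_stage("calibration", config$out_dir, {
    fr <- config$fricke
    if (!is.null(fr$C)) {
      cf <- default_conversion_factor(); cf$C <- as_C(fr$C); cf
    } else if (!is.null(fr$csv)) {
      if (file.exists(fr$csv))
        input_hashes[basename(fr$csv)] <- unname(tools::md5sum(fr$csv))
      fit_conversion_factor(read_calibration_csv(fr$csv))
    } else {
      fit_conversion_factor(
        simulate_fricke_series(fr$simulate,
                               seed = derive_seed(config$seed, 101L)))
    }
  })
  bundle$conversion_factor <- data.frame(C_Gy_per_MBq_h = calib$C,
                                         residual_sd_Gy = calib$residual_sd,
                                         n = calib$n)

  bundle$dose <- run_stage("dose", config$out_dir, {
    do.call(rbind, lapply(names(branches), function(nm) {
      b <- branches[[nm]]
      masses <- vapply(b$mbq_unc, function(tc) tc$mass_g, numeric(1))
      if (any(!is.finite(masses)))
        stop("missing ROI mass for dose table (tracer '", nm, "')")
      cbind(tracer = nm,
            dose_table(b$mbq_unc, masses, C = calib,
                       nuclide = config$nuclide,
                       include_tail = config$include_tail),
            stringsAsFactors = FALSE)
    }))
  })

  resp <- run_stage("response", config$out_dir, {
    gr <- config$growth
    growth <- if (!is.null(gr$csv)) {
      if (!file.exists(gr$csv))
        stop("growth CSV not found: ", gr$csv)
      input_hashes[basename(gr$csv)] <- unname(tools::md5sum(gr$csv))
      read_growth_csv(gr$csv)
    } else {
      simulate_growth(gr$simulate, seed = derive_seed(config$seed, 201L))
    }
    rs <- response_summary(growth, control_group = config$control_group)
    per <- attr(rs, "per_animal")
    unc <- per[!per$censored, ]
    vals <- split(unc$five_td_days, unc$group)
    vals <- vals[c(config$control_group,
                   setdiff(names(vals), config$control_group))]
    gt <- group_tests(vals, control = config$control_group,
                      comparisons = config$posthoc, nsim = config$nsim,
                      seed = derive_seed(config$seed, 301L))
    list(summary = rs, tests = gt, growth = growth)
  })
  bundle$response <- resp$summary
  bundle$stats <- cbind(resp$tests$anova[rep(1L, nrow(resp$tests$comparisons)),
                                         c("F", "df1", "df2")],
                        resp$tests$comparisons)
  rownames(bundle$stats) <- NULL

  run_stage("write", config$out_dir, {
    utils::write.csv(bundle$residence_time,
                     file.path(config$out_dir, "residence_time.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$ratios, file.path(config$out_dir, "ratios.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$dose, file.path(config$out_dir, "dose.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(unclass(bundle$response)),
                     file.path(config$out_dir, "response_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$stats, file.path(config$out_dir, "stats.csv"),
                     row.names = FALSE)
    manifest <- list(
      package = "theradose",
      version = as.character(utils::packageVersion("theradose")),
      seed = config$seed,
      nuclide = config$nuclide$name,
      half_life_min = config$nuclide$half_life_min,
      A0_mode = if (is.null(config$A0)) "whole-body" else "nominal",
      A0 = config$A0 %||% NA,
      conversion_factor = calib$C,
      include_tail = config$include_tail,
      tail = config$tail,
      posthoc = config$posthoc,
      nsim = config$nsim,
      control_group = config$control_group,
      input_hashes = as.list(input_hashes))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  bundle$manifest_path <- file.path(config$out_dir, "manifest.json")
  bundle$out_dir <- config$out_dir
  class(bundle) <- "theradose_bundle"
  report <- render_report(bundle)
  writeLines(report, file.path(config$out_dir, "report.txt"))
  invisible(bundle)
}

#' @export
print.theradose_bundle <- function(x, ...) {
  cat("<theradose_bundle> tables:",
      paste(setdiff(names(x), c("manifest_path", "out_dir")),
            collapse = ", "),
      "\n  written to:", x$out_dir, "\n")
  invisible(x)
}

fmt_table_section <- function(title, tab) {
  if (is.null(tab) || (is.data.frame(tab) && nrow(tab) == 0L))
    return(c(paste0("== ", title, " =="), "[absent]", ""))
  c(paste0("== ", title, " =="),
    utils::capture.output(print.data.frame(as.data.frame(tab), digits = 4,
                                           row.names = FALSE)),
    "")
}

#' Render a human-readable report from a pipeline bundle
#'
#' Emits text sections shaped like the study's summary tables: response
#' (treatment, 5Td, TGD, EF, significance), per-organ absorbed dose, and
#' tumor-to-tissue ratios, plus residence times and the ANOVA.  A missing
#' table renders as `[absent]`; in strict mode that is an error.
#'
#' @param bundle A `theradose_bundle` from [run_pipeline()].
#' @param strict Error on missing tables.
#' @return Character vector of report lines.
#' @export
render_report <- function(bundle, strict = FALSE) {
  stopifnot(inherits(bundle, "theradose_bundle") || is.list(bundle))
  wanted <- c("response", "dose", "ratios", "residence_time", "stats")
  if (strict) {
    missing <- wanted[vapply(wanted, function(w)
      is.null(bundle[[w]]) || nrow(as.data.frame(bundle[[w]])) == 0L,
      logical(1))]
    if (length(missing))
      stop("missing table(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  resp <- bundle$response
  resp_tab <- if (is.null(resp)) NULL else
    data.frame(treatment = resp$group,
               five_td_days = sprintf("%.2f +/- %.2f", resp$mean_5td_days,
                                      resp$sd_5td_days),
               tgd_days = round(resp$tgd_days, 2),
               ef = round(resp$ef, 2), stringsAsFactors = FALSE)
  c("theradose pipeline report",
    "=========================", "",
    fmt_table_section("Tumor response (5Td / TGD / EF)", resp_tab),
    fmt_table_section("Group statistics", bundle$stats),
    fmt_table_section("Mean absorbed dose (Gy)", bundle$dose),
    fmt_table_section("Tumor-to-tissue ratios", bundle$ratios),
    fmt_table_section("Residence times (h)", bundle$residence_time))
}
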