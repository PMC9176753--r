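# Declarative pipeline runner: a config lists the stages in order; outputs
# and a plain-text run log are written for reproducibility. The same config
# and seed always produce identical exports.

.stage_order <- c(synth = 0, load = 0, ignore = 1,
                  correct_media = 2, correct_od = 2, correct_auto = 2,
                  getstats = 3, common_time = 4, monod = 5,
                  export = 6, plot_plate = 6)

#' Run an analysis pipeline from a declarative config
#'
#' The config (a list, or a path to a YAML file) holds a \code{seed}, an
#' \code{outdir} and an ordered list of \code{stages}. Each stage is a list
#' with a \code{stage} name -- one of \code{synth}, \code{load},
#' \code{ignore}, \code{correct_media}, \code{correct_od},
#' \code{correct_auto}, \code{getstats}, \code{common_time}, \code{monod},
#' \code{export}, \code{plot_plate} -- plus that stage's parameters. Stages
#' must respect the natural order (load before corrections before
#' statistics); violations raise an error naming the stage.
#'
#' @param config List or YAML path.
#' @param outdir Overrides the config's output directory.
#' @return Invisibly, a list with the final \code{plate_dataset} and any
#'   stage products (e.g. the Monod fit).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$stages))
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  outdir <- if (!is.null(outdir)) outdir
    else if (!is.null(config$outdir)) config$outdir else "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  names_seq <- vapply(config$stages, `[[`, "", "stage")
  unknown <- setdiff(names_seq, names(.stage_order))
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  ranks <- .stage_order[names_seq]
  if (is.unsorted(ranks))
    stop("config-order error: stage '",
         names_seq[which(diff(ranks) < 0)[1] + 1],
         "' appears after a later-phase stage")
  if (!names_seq[1] %in% c("synth", "load"))
    stop("config-order error: pipeline must start with 'synth' or 'load'")

  ds <- NULL; products <- list()
  need_ds <- function(stage) {
    if (is.null(ds)) stop("config-order error: stage '", stage,
                          "' before any dataset is loaded")
  }
  for (k in seq_along(config$stages)) {
    st <- config$stages[[k]]
    p <- st[setdiff(names(st), "stage")]
    ds <- switch(st$stage,
      synth = {
        spec_args <- p[intersect(names(p), names(formals(synth_plate_spec)))]
        spec_args$seed <- if (is.null(p$seed)) seed else p$seed
        spec <- do.call(synth_plate_spec, spec_args)
        gen <- generate_plate(spec, dir = outdir,
                              stem = if (is.null(p$stem)) "plate" else p$stem)
        products$synth_truth <- gen$truth
        load_plate(gen$data_file, gen$contents_file,
                   experiment = if (is.null(p$experiment)) "synth" else p$experiment)
      },
      load = load_plate(p$data, p$contents,
                        experiment = if (is.null(p$experiment)) "exp1" else p$experiment),
      ignore = { need_ds("ignore"); ignore_wells(ds, unlist(p$wells)) },
      correct_media = { need_ds("correct_media")
        do.call(correct_media, c(list(ds), p)) },
      correct_od = { need_ds("correct_od")
        correct_od(ds, calibration = p$calibration) },
      correct_auto = { need_ds("correct_auto")
        method <- if (is.null(p$method)) "unmix" else p$method
        cf <- if (method == "unmix")
          correct_gfp(ds, tagged = p$tagged, untagged = p$untagged,
                      r_g = if (is.null(p$r_g)) 0 else p$r_g)
        else correct_auto_by_od(ds, tagged = p$tagged, untagged = p$untagged,
                                fluorophore = if (is.null(p$fluorophore))
                                  "F525" else p$fluorophore)
        products$corrected_fluorescence <- cf
        attach_fluorescence(ds, cf)
      },
      getstats = { need_ds("getstats")
        args <- p[intersect(names(p), names(formals(get_growth_stats)))]
        if (is.null(args$seed)) args$seed <- seed
        do.call(get_growth_stats, c(list(ds), args)) },
      common_time = { need_ds("common_time")
        add_common_time(ds, spacing = p$spacing) },
      monod = { need_ds("monod")
        if (is.null(ds$summary))
          stop("config-order error: 'monod' needs 'getstats' first")
        ds2 <- add_numeric_column(ds, token = p$token, name = "conc")
        y <- if (is.null(p$stat)) "local_max_gr" else p$stat
        sm <- ds2$summary
        mu <- sm[[y]]
        miss <- is.na(mu) | is.na(sm$conc)
        fit <- fit_monod(sm$conc[!miss], mu[!miss],
                         bootstrap_n = if (is.null(p$bootstrap_n)) 100
                           else p$bootstrap_n,
                         seed = seed)
        products$monod <- fit
        ds2 },
      export = { need_ds("export")
        fmt <- if (is.null(p$format)) "tsv" else p$format
        stem <- if (is.null(p$stem)) "tables" else p$stem
        export_dataset(ds, file.path(outdir, stem), format = fmt)
        ds },
      plot_plate = { need_ds("plot_plate")
        f <- file.path(outdir, paste0("plate_",
          if (is.null(p$signal)) "OD" else p$signal, ".pdf"))
        grDevices::pdf(f, width = 12, height = 8)
        plot_plate(ds, signal = if (is.null(p$signal)) "OD" else p$signal)
        grDevices::dev.off()
        ds })
  }
  if (!is.null(ds)) write_run_log(ds, file.path(outdir, "run_log.txt"))
  invisible(c(list(dataset = ds), products))
}
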