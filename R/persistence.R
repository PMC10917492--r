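`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist a fitted model as text arrays plus a JSON manifest
#'
#' Writes a [fit_met_model()] result into a directory: one CSV per draw
#' block (`g.csv`, `l.csv`, `gl.csv`, ..., `scales.csv`, `sigma.csv`,
#' `yrep.csv`, `loglik.csv`), the validated data (`met.csv`) and a
#' `manifest.json` recording the model spec, the column layout, parameter
#' shapes and the chain layout. [read_met_fit()] reconstructs the fit
#' exactly (the index maps are rebuilt deterministically from the data and
#' spec), so fit artifacts are reusable across probability runs with
#' different selection intensities.
#'
#' @param fit a `met_fit`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_met_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "met_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, file) {
    utils::write.csv(as.data.frame(m), file.path(dir, file), row.names = FALSE)
  }
  for (nm in names(fit$draws)) wm(fit$draws[[nm]], paste0(nm, ".csv"))
  wm(fit$scales, "scales.csv")
  wm(fit$s_sig, "s_sig.csv")
  wm(fit$sigma, "sigma.csv")
  wm(fit$yrep, "yrep.csv")
  wm(fit$loglik, "loglik.csv")
  write_met_table(fit$met, file.path(dir, "met.csv"))
  manifest <- list(
    package = "probmet",
    spec = unclass(fit$spec),
    phi = fit$phi,
    families = fit$families,
    columns = list(
      reg = length(fit$met$regions) > 0,
      year = length(fit$met$years) > 0,
      repl = !is.null(fit$met$records$repl),
      block = !is.null(fit$met$records$block)
    ),
    shapes = lapply(fit$draws, dim),
    chain = fit$chain, iteration = fit$iteration,
    sampler = fit$sampler
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_met_fit
#' @export
read_met_fit <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  cols <- man$columns
  met <- read_met_table(file.path(dir, "met.csv"),
                        gen = "gen", loc = "loc", trait = "value",
                        reg = if (isTRUE(cols$reg)) "reg" else NULL,
                        year = if (isTRUE(cols$year)) "year" else NULL,
                        repl = if (isTRUE(cols$repl)) "repl" else NULL,
                        block = if (isTRUE(cols$block)) "block" else NULL)
  sp <- man$spec
  spec <- met_model_spec(design = sp$design, use_region = sp$use_region,
                         use_year = sp$use_year, res_het = sp$res_het,
                         phi = man$phi, n_iter = sp$n_iter,
                         n_chains = sp$n_chains, n_warmup = sp$n_warmup,
                         seed = sp$seed)
  model <- build_met_model(met, spec)  # deterministic index maps
  rm_ <- function(file) as.matrix(utils::read.csv(file.path(dir, file),
                                                  check.names = FALSE))
  draws <- lapply(stats::setNames(names(man$shapes), names(man$shapes)),
                  function(nm) rm_(paste0(nm, ".csv")))
  yrep <- rm_("yrep.csv"); dimnames(yrep) <- NULL
  loglik <- rm_("loglik.csv"); dimnames(loglik) <- NULL
  structure(list(draws = draws, scales = rm_("scales.csv"),
                 s_sig = rm_("s_sig.csv"), sigma = rm_("sigma.csv"),
                 yrep = yrep, loglik = loglik,
                 chain = man$chain, iteration = man$iteration,
                 index = model$index, families = model$families,
                 phi = man$phi, spec = spec, met = met,
                 sampler = list(
                   backend = man$sampler$backend,
                   divergences = man$sampler$divergences %||% NA_integer_,
                   treedepth_hits = man$sampler$treedepth_hits %||% NA_integer_,
                   bfmi = man$sampler$bfmi %||% NA_real_)),
            class = "met_fit")
}
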