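#' Load and validate a run configuration
#'
#' Configurations are YAML files (or equivalent R lists) naming a circuit
#' motif, its parameters, the transcription-factor block(s), an effector
#' protocol and an analysis. Concentrations accept unit suffixes
#' (see [parse_conc()]); unknown keys are rejected with an error naming the
#' offending key. A configuration may start from a [preset()] via the
#' `preset:` key and override individual fields.
#'
#' Schema (top level): `preset` (optional), `motif` (one of `auto`, `hill`,
#' `mutual_repression`, `cffl`, `iffl`), `tf` / `tf1` / `tf2` / `tfX` / `tfY`
#' blocks (`K_A`, `K_I`, `eps`, `n_sites`), `params` (motif parameters),
#' `protocol` (`type: constant|step|ramp` plus its concentrations/times),
#' `analysis` (`name` plus `options`), `output` (`path`, `format`).
#'
#' @param x Path to a YAML file, or a list with the same structure.
#' @return An object of class `run_config`: the validated list with a built
#'   `params` object and normalised concentrations.
#' @export
load_config <- function(x) {
  cfg <- if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    yaml::read_yaml(x)
  } else if (is.list(x)) x else stop("'x' must be a file path or a list")
  allowed <- c("preset", "motif", "tf", "tf1", "tf2", "tfX", "tfY",
               "params", "protocol", "analysis", "output")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))

  obj <- NULL
  if (!is.null(cfg$preset)) {
    obj <- preset(cfg$preset)
    if (is.null(cfg$motif))
      cfg$motif <- switch(class(obj)[1],
                          auto_params = "auto",
                          hill_auto_params = "hill",
                          mr_params = "mutual_repression",
                          cffl_params = "cffl",
                          iffl_params = "iffl",
                          NULL)
  }

  build_tf <- function(block) {
    allowed_tf <- c("K_A", "K_I", "eps", "n_sites")
    bad <- setdiff(names(block), allowed_tf)
    if (length(bad)) stop("unknown tf key(s): ", paste(bad, collapse = ", "))
    allosteric_tf(block$K_A, block$K_I, block$eps,
                  if (is.null(block$n_sites)) 2L else block$n_sites)
  }
  tf_main <- if (!is.null(cfg$tf)) build_tf(cfg$tf) else preset("mwc_tf")

  pp <- cfg$params
  check_params_keys <- function(allowed) {
    bad <- setdiff(names(pp), allowed)
    if (length(bad)) stop("unknown params key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$motif) && (is.null(obj) || !is.null(pp))) {
    merged <- function(defaults) {
      for (nm in names(pp)) defaults[[nm]] <- pp[[nm]]
      defaults
    }
    obj <- switch(cfg$motif,
      auto = {
        check_params_keys(c("r0", "r1", "r2", "omega"))
        d <- if (inherits(obj, "auto_params"))
          obj[c("r0", "r1", "r2", "omega")] else list()
        d <- merged(d)
        auto_params(d$r0, d$r1, d$r2, d$omega, tf = tf_main)
      },
      hill = {
        check_params_keys(c("n", "r0", "r2", "Kd_eff", "gamma"))
        d <- if (inherits(obj, "hill_auto_params"))
          obj[c("n", "r0", "r2", "Kd_eff", "gamma")] else list()
        d <- merged(d)
        hill_auto_params(d$n, d$r0, d$r2, d$Kd_eff, d$gamma, tf = tf_main)
      },
      mutual_repression = {
        check_params_keys(c("rbar", "omega1", "omega2", "Kratio"))
        d <- if (inherits(obj, "mr_params"))
          obj[c("rbar", "omega1", "omega2", "Kratio")]
          else list(Kratio = 1)
        d <- merged(d)
        tf1 <- if (!is.null(cfg$tf1)) build_tf(cfg$tf1) else tf_main
        tf2 <- if (!is.null(cfg$tf2)) build_tf(cfg$tf2) else tf1
        mr_params(d$rbar, d$omega1, d$omega2, d$Kratio, tf1 = tf1, tf2 = tf2)
      },
      cffl = ,
      iffl = {
        base <- c("r0Y", "r1Y", "r0Z", "r1Z", "omega", "KXZ", "KYZ", "Xbar")
        if (cfg$motif == "cffl") base <- c(base, "r2Z")
        check_params_keys(base)
        keep <- intersect(base, names(obj))
        d <- if (inherits(obj, "ffl_params")) obj[keep]
          else list(KXZ = 1, KYZ = 1, Xbar = 1)
        d <- merged(d)
        tfX <- if (!is.null(cfg$tfX)) build_tf(cfg$tfX) else tf_main
        tfY <- if (!is.null(cfg$tfY)) build_tf(cfg$tfY) else tfX
        if (cfg$motif == "cffl")
          cffl_params(d$r0Y, d$r1Y, d$r0Z, d$r1Z, d$r2Z, d$omega,
                      d$KXZ, d$KYZ, d$Xbar, tfX = tfX, tfY = tfY)
        else
          iffl_params(d$r0Y, d$r1Y, d$r0Z, d$r1Z, d$omega,
                      d$KXZ, d$KYZ, d$Xbar, tfX = tfX, tfY = tfY)
      },
      stop("unknown motif: ", cfg$motif))
  }
  if (is.null(obj)) stop("configuration must name a 'motif' or a 'preset'")

  proto <- cfg$protocol
  if (!is.null(proto)) {
    ptype <- proto$type
    if (is.null(ptype)) stop("protocol block requires a 'type'")
    proto <- switch(ptype,
      constant = {
        bad <- setdiff(names(proto), c("type", "c", "c1", "c2", "cX", "cY"))
        if (length(bad)) stop("unknown protocol key(s): ",
                              paste(bad, collapse = ", "))
        lapply(proto, function(v)
          if (is.character(v) && v %in% c("constant")) v else parse_conc(v))
      },
      step = {
        bad <- setdiff(names(proto),
                       c("type", "c_initial", "c_final", "cY", "t_step"))
        if (length(bad)) stop("unknown protocol key(s): ",
                              paste(bad, collapse = ", "))
        s <- step_input(proto$c_initial, proto$c_final,
                        cY = if (is.null(proto$cY)) 1e-7 else proto$cY,
                        t_step = if (is.null(proto$t_step)) 0 else proto$t_step)
        c(list(type = "step"), unclass(s))
      },
      ramp = {
        bad <- setdiff(names(proto),
                       c("type", "c_from", "c_to", "t_start", "t_end", "cY"))
        if (length(bad)) stop("unknown protocol key(s): ",
                              paste(bad, collapse = ", "))
        r <- ramp_input(proto$c_from, proto$c_to, proto$t_start, proto$t_end,
                        cY = if (is.null(proto$cY)) 1e-7 else proto$cY)
        c(list(type = "ramp"), unclass(r))
      },
      stop("unknown protocol type: ", ptype))
  }

  structure(list(motif = cfg$motif, params = obj, protocol = proto,
                 analysis = cfg$analysis, output = cfg$output),
            class = "run_config")
}

#' Run a configured analysis
#'
#' Dispatches a validated [load_config()] object to the matching analysis
#' routine and (optionally) writes the resulting table to
#' `output$path` in `output$format` (`csv`, `tsv` or `json`), at full float
#' precision and with deterministic row ordering. Supported analyses:
#' `pact`, `fixed_points`, `bifurcate`, `bistable_range`,
#' `necessary_conditions`, `hysteresis`, `compare_hill`, `bimap2d`,
#' `geometry`, `feasibility`, `diagonal_transition`, `relax`, `basins`,
#' `separatrix`, `ffl_delay`, `ffl_sweep`, `ffl_pulse`, `ffl_ramp`.
#'
#' @param cfg A `run_config` (or anything [load_config()] accepts).
#' @return A list with `table` (data frame), `result` (the full analysis
#'   object) and `log` (parameters, analysis name, timing), invisibly.
#' @export
run_analysis <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- load_config(cfg)
  if (is.null(cfg$analysis) || is.null(cfg$analysis$name))
    stop("configuration has no analysis block")
  name <- cfg$analysis$name
  opts <- cfg$analysis$options
  if (is.null(opts)) opts <- list()
  p <- cfg$params
  proto <- cfg$protocol
  t0 <- proc.time()[["elapsed"]]
  getopt <- function(key, default) if (is.null(opts[[key]])) default else opts[[key]]
  need_proto <- function(type) {
    if (is.null(proto) || !identical(proto$type, type))
      stop(sprintf("analysis '%s' requires a '%s' protocol block", name, type))
  }
  grid_opt <- function(key, lo, hi, n)
    log_grid(parse_conc(getopt(paste0(key, "_min"), lo)),
             parse_conc(getopt(paste0(key, "_max"), hi)),
             getopt(paste0(key, "_n"), n))

  res <- switch(name,
    pact = {
      tf <- if (is_allosteric_tf(p)) p else p$tf
      if (is.null(tf) && inherits(p, "mr_params")) tf <- p$tf1
      if (is.null(tf) && inherits(p, "ffl_params")) tf <- p$tfX
      cg <- grid_opt("c", 1e-12, 1e-2, getopt("n", 200))
      data.frame(c = cg, pact = p_active(tf, cg))
    },
    fixed_points = {
      need_proto("constant")
      if (inherits(p, "auto_params")) {
        fp <- auto_fixed_points(p, proto$c)
        cbind(c = proto$c, fp)
      } else if (inherits(p, "mr_params")) {
        fp <- mr_fixed_points(p, proto$c1, proto$c2)
        cbind(c1 = proto$c1, c2 = proto$c2, fp)
      } else stop("fixed_points supports the auto and mutual_repression motifs")
    },
    bifurcate = {
      stopifnot(inherits(p, "auto_params"))
      bd <- auto_bifurcation(p, grid_opt("c", 1e-9, 1e-2, getopt("n", 200)))
      bd$points
    },
    bistable_range = {
      stopifnot(inherits(p, "auto_params"))
      bd <- auto_bifurcation(p, grid_opt("c", 1e-9, 1e-2, getopt("n", 200)))
      bd$bistable
    },
    necessary_conditions = {
      stopifnot(inherits(p, "auto_params"))
      nc <- necessary_conditions_auto(p)
      as.data.frame(nc)
    },
    hysteresis = {
      stopifnot(inherits(p, "auto_params"))
      cg <- grid_opt("c", 1e-9, 1e-2, getopt("n", 200))
      if (identical(getopt("direction", "up"), "down")) cg <- rev(cg)
      hysteresis(p, cg, getopt("A_init", 0))
    },
    compare_hill = {
      sc <- preset("hill_compare")
      omega <- getopt("omega", if (inherits(p, "auto_params")) p$omega else 7.5)
      tf <- if (inherits(p, "circuit_params")) p$tf else preset("mwc_tf")
      compare_hill_thermo(sc$r0, sc$r1, sc$r2, sc$gamma, sc$Kd, omega, tf,
                          c_grid = grid_opt("c", 1e-9, 1e-2, getopt("n", 120)))
    },
    bimap2d = {
      stopifnot(inherits(p, "mr_params"))
      m <- mr_bistability_map(p, grid_opt("c1", 1e-7, 1e-4, getopt("n", 40)),
                              grid_opt("c2", 1e-7, 1e-4, getopt("n", 40)))
      data.frame(c1 = rep(m$c1_grid, times = length(m$c2_grid)),
                 c2 = rep(m$c2_grid, each = length(m$c1_grid)),
                 bistable = as.vector(m$bistable))
    },
    geometry = {
      stopifnot(inherits(p, "mr_params"))
      m <- mr_bistability_map(p, grid_opt("c1", 1e-7, 1e-4, getopt("n", 40)),
                              grid_opt("c2", 1e-7, 1e-4, getopt("n", 40)))
      data.frame(geometry = mr_geometry_class(m))
    },
    feasibility = {
      stopifnot(inherits(p, "mr_params"))
      og <- log_grid(getopt("omega_min", 0.5), getopt("omega_max", 50),
                     getopt("omega_n", 6))
      fb <- mr_feasibility_boundary(p$rbar, og, og, p$tf1)
      data.frame(omega1 = rep(og, times = length(og)),
                 omega2 = rep(og, each = length(og)),
                 feasible = as.vector(fb$feasible))
    },
    diagonal_transition = {
      stopifnot(inherits(p, "mr_params"))
      data.frame(c_transition = mr_diagonal_transition(p))
    },
    relax = {
      stopifnot(inherits(p, "auto_params"))
      need_proto("constant")
      a0 <- getopt("A0", 30)
      do.call(rbind, lapply(a0, function(A0) {
        r <- relaxation_time_auto(p, proto$c, A0,
                                  method = getopt("method", "fit_exponential"))
        data.frame(A0 = A0, tau = r$tau, attractor = r$target_state)
      }))
    },
    basins = {
      stopifnot(inherits(p, "mr_params"))
      need_proto("constant")
      g <- seq(getopt("R_min", 0.01), getopt("R_max", 2),
               length.out = getopt("n", 20))
      b <- mr_basins(p, proto$c1, proto$c2, g, g)
      data.frame(R1 = rep(g, times = length(g)),
                 R2 = rep(g, each = length(g)),
                 basin = as.vector(b$label), tau = as.vector(b$tau))
    },
    separatrix = {
      stopifnot(inherits(p, "mr_params"))
      need_proto("constant")
      mr_separatrix(p, proto$c1, proto$c2)
    },
    ffl_delay = {
      stopifnot(inherits(p, "ffl_params"))
      need_proto("step")
      s <- step_input(proto$c_initial, proto$c_final, proto$cY, proto$t_step)
      da <- delay_analytics(p, s, check = getopt("check", FALSE))
      data.frame(direction = da$direction, DeltaY = da$DeltaY, Phi = da$Phi,
                 S = da$S, avg_dt = da$avg_dt, Z_i = da$Z_i, Z_f = da$Z_f)
    },
    ffl_sweep = {
      stopifnot(inherits(p, "ffl_params"))
      need_proto("step")
      s <- step_input(proto$c_initial, proto$c_final, proto$cY, proto$t_step)
      n <- getopt("n", 50)
      sw <- delay_sweep(p, s,
                        KXZ_grid = log_grid(getopt("K_min", 1e-2),
                                            getopt("K_max", 1e2), n),
                        KYZ_grid = log_grid(getopt("K_min", 1e-2),
                                            getopt("K_max", 1e2), n),
                        pulses = getopt("pulses", FALSE))
      data.frame(KXZ = rep(sw$KXZ_grid, times = length(sw$KYZ_grid)),
                 KYZ = rep(sw$KYZ_grid, each = length(sw$KXZ_grid)),
                 avg_dt = as.vector(sw$avg_dt))
    },
    ffl_pulse = {
      stopifnot(inherits(p, "ffl_params"))
      need_proto("step")
      s <- step_input(proto$c_initial, proto$c_final, proto$cY, proto$t_step)
      tr <- ffl_step_response(p, s)
      pm <- pulse_metrics(tr)
      data.frame(has_pulse = pm$has_pulse, strong = pm$strong,
                 amplitude = pm$amplitude, t_peak = pm$t_peak)
    },
    ffl_ramp = {
      stopifnot(inherits(p, "ffl_params"))
      need_proto("ramp")
      r <- ramp_input(proto$c_from, proto$c_to, proto$t_start, proto$t_end,
                      proto$cY)
      cr <- continuous_response(p, r)
      data.frame(t = cr$ffl$t, Y = cr$ffl$y[, 1], Z = cr$ffl$y[, 2],
                 Z_simple = cr$simple$y[, 1], t_c = cr$t_c)
    },
    stop(sprintf("unknown analysis '%s'", name)))

  tbl <- as.data.frame(res)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!is.null(cfg$output) && !is.null(cfg$output$path))
    write_result_table(tbl, cfg$output$path,
                       if (is.null(cfg$output$format)) "csv"
                       else cfg$output$format)
  invisible(list(table = tbl, result = res,
                 log = list(analysis = name, motif = cfg$motif,
                            elapsed_s = elapsed,
                            package_version =
                              as.character(utils::packageVersion("inducible")))))
}

write_result_table <- function(tbl, path, format = c("csv", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(tbl, path, digits = NA, auto_unbox = TRUE)
    return(invisible(path))
  }
  out <- tbl
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 17, format = "g"))
  utils::write.table(out, path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
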