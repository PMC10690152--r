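## Trajectory I/O, pre-filters, and the end-to-end five-step heterogeneity
## protocol: filter -> denoise per bead -> coarse classify -> homogeneity per
## coarse group -> mixture clustering within heterogeneous groups ->
## homogeneity per cluster -> per-cluster moduli by all three GSER protocols.

#' Read tracked-bead trajectories from a CSV table
#'
#' Expects columns `bead_id, frame, x, y` (micrometres), one row per bead
#' per frame. Rows are sorted by frame within bead; the frame interval
#' `tau` comes from the experiment configuration, not the file.
#'
#' @param path CSV file path.
#' @param tau Frame interval (s).
#' @return A named list of [trajectory_record()] objects.
#' @export
read_trajectories <- function(path, tau) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("bead_id", "frame", "x", "y")
  if (!all(need %in% names(df)))
    stop("trajectory table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("empty trajectory file: ", path)
  for (cc in c("frame", "x", "y")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop(sprintf("non-numeric '%s' value at row %d", cc, bad[1L]))
    if (anyNA(v)) stop(sprintf("missing '%s' value in %s", cc, path))
    df[[cc]] <- v
  }
  if (anyDuplicated(df[c("bead_id", "frame")]))
    stop("duplicate (bead_id, frame) rows in ", path)
  out <- lapply(split(df, df$bead_id), function(b) {
    b <- b[order(b$frame), ]
    trajectory_record(cbind(x = b$x, y = b$y), tau, bead_id = b$bead_id[1L],
                      frame_index = as.integer(b$frame))
  })
  out[order(names(out))]
}

#' Write trajectories to the CSV table format
#'
#' @param records List of `trajectory_record` objects (d = 2).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(records, path) {
  rows <- lapply(records, function(tr) {
    data.frame(bead_id = tr$bead_id, frame = tr$frame_index,
               x = tr$positions[, 1L], y = tr$positions[, 2L])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write the ground-truth sidecar of a simulated ensemble
#'
#' @param truth The `truth` data frame from [simulate_ensemble()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Proximity pre-filter
#'
#' Beads closer than `factor` diameters at any temporally shared frame may
#' interact hydrodynamically; both members of every violating pair are
#' excluded (conservative: the rule requires isolation but does not say
#' which member to keep). Beads tracked at disjoint times cannot interact
#' and are never compared.
#'
#' @param records List of `trajectory_record` objects.
#' @param diameter Bead diameter (um).
#' @param factor Required separation in diameters (default 5).
#' @return A list with `retained` (records) and `exclusions` (data frame of
#'   offending pairs, first offending frame and distance).
#' @export
proximity_filter <- function(records, diameter, factor = 5) {
  M <- length(records)
  bad <- logical(M)
  log_rows <- list()
  if (M >= 2L) for (i in 1:(M - 1L)) for (j in (i + 1L):M) {
    fi <- records[[i]]$frame_index; fj <- records[[j]]$frame_index
    shared <- intersect(fi, fj)
    if (length(shared) == 0L) next
    pi_ <- records[[i]]$positions[match(shared, fi), , drop = FALSE]
    pj_ <- records[[j]]$positions[match(shared, fj), , drop = FALSE]
    dist2 <- rowSums((pi_ - pj_)^2)
    hit <- which(dist2 < (factor * diameter)^2)
    if (length(hit)) {
      bad[i] <- bad[j] <- TRUE
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        bead_a = records[[i]]$bead_id, bead_b = records[[j]]$bead_id,
        frame = shared[hit[1L]], distance = sqrt(dist2[hit[1L]]))
    }
  }
  list(retained = records[!bad],
       exclusions = if (length(log_rows)) do.call(rbind, log_rows)
                    else data.frame(bead_a = character(0L), bead_b = character(0L),
                                    frame = integer(0L), distance = numeric(0L)))
}

#' Uniformity pre-filter
#'
#' Enforces a common frame interval and series length: records with any
#' missing frame are dropped, records longer than `required_N` increments
#' are truncated to their first `required_N + 1` positions, and shorter
#' records are dropped.
#'
#' @param records List of `trajectory_record` objects.
#' @param required_N Required number of increments.
#' @return A list with `retained` and `dropped` (data frame of bead ids and
#'   reasons).
#' @export
uniformity_filter <- function(records, required_N) {
  keep <- list(); dropped <- list()
  for (tr in records) {
    if (any(diff(tr$frame_index) != 1L)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(bead_id = tr$bead_id, reason = "missing_frames")
      next
    }
    N <- n_increments(tr)
    if (N < required_N) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(bead_id = tr$bead_id, reason = "too_short")
      next
    }
    if (N > required_N) {
      tr$positions <- tr$positions[seq_len(required_N + 1L), , drop = FALSE]
      tr$frame_index <- tr$frame_index[seq_len(required_N + 1L)]
    }
    keep[[length(keep) + 1L]] <- tr
  }
  list(retained = keep,
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else data.frame(bead_id = character(0L), reason = character(0L)))
}

#' Protocol configuration
#'
#' Assembles (and defaults) the configuration consumed by
#' [run_protocol()]. A YAML file of flat key-value pairs may be supplied
#' instead via `config_file` on [run_protocol()].
#'
#' @param tau Frame interval (s).
#' @param N Required increments per bead.
#' @param bead_diameter Bead diameter (um).
#' @param temperature Absolute temperature (K).
#' @param viscosity Reference-fluid viscosity (Pa s).
#' @param Kmax Maximum mixture components per coarse group.
#' @param epsilon Homogeneity test level.
#' @param proximity_factor Required separation in diameters.
#' @param noise_cutoff Noise-floor cutoff on alpha.
#' @param omega_points Frequency grid size for moduli curves.
#' @param seed Integer seed recorded and used for any stochastic stage.
#' @return A named list of class `protocol_config`.
#' @export
protocol_config <- function(tau = 1 / 60, N = 1800, bead_diameter = 1,
                            temperature = 293.15, viscosity = 1.002e-3,
                            Kmax = 4, epsilon = 0.05, proximity_factor = 5,
                            noise_cutoff = 0.1, omega_points = 50,
                            seed = 1L) {
  structure(as.list(environment()), class = "protocol_config")
}

.group_homogeneity <- function(tab, fits, epsilon) {
  idx <- match(tab$bead_id, vapply(fits, `[[`, character(1L), "bead_id"))
  ests <- cbind(alpha = tab$alpha, logDelta = log(tab$delta))
  covs <- lapply(fits[idx], classifier_covariance)
  usable <- vapply(covs, function(V) all(is.finite(V)), logical(1L))
  if (sum(usable) < 2L) return(NULL)
  cochran_q(ests[usable, , drop = FALSE], covs[usable], epsilon = epsilon)
}

#' Run the five-step heterogeneity protocol
#'
#' Executes the full analysis on a set of trajectories: (0) proximity and
#' uniformity pre-filters; (1) LS-predictor/fARMAs-corrector denoising per
#' bead and coarse classification into water-like, flake-like and
#' noise-floor groups (noise-floor beads are reported but never contribute
#' to moduli); (2) Cochran's Q homogeneity test per coarse signal group;
#' (3) when a group is rejected as non-homogeneous, normal-mixture
#' clustering within it with BIC model selection; (4) homogeneity per
#' cluster (clusters of fewer than 4 beads annotated low-power); (5)
#' per-cluster dynamic moduli by the GSER Average protocol alongside the
#' MSD Average and Classifier Average comparisons.
#'
#' @param trajectories List of `trajectory_record` objects, or `NULL` to
#'   read from `trajectory_file`.
#' @param config A [protocol_config()] (or a list of overrides).
#' @param trajectory_file Optional CSV path read with [read_trajectories()].
#' @param config_file Optional YAML file of flat key-value overrides.
#' @return An object of class `protocol_report`: classifier table, coarse
#'   labels, per-group and per-cluster homogeneity, cluster assignments,
#'   moduli curves per cluster and method, filter logs, and provenance.
#' @export
run_protocol <- function(trajectories = NULL, config = protocol_config(),
                         trajectory_file = NULL, config_file = NULL) {
  if (!is.null(config_file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading config files requires the 'yaml' package")
    config <- utils::modifyList(protocol_config(), yaml::read_yaml(config_file))
  } else if (!inherits(config, "protocol_config")) {
    config <- utils::modifyList(protocol_config(), as.list(config))
  }
  cfg <- config
  if (is.null(trajectories)) {
    if (is.null(trajectory_file)) stop("no trajectories supplied")
    trajectories <- read_trajectories(trajectory_file, cfg$tau)
  }
  if (length(trajectories) == 0L) stop("no trajectories supplied")
  set.seed(cfg$seed)
  ctx <- material_context(radius = cfg$bead_diameter / 2 * 1e-6,
                          temperature = cfg$temperature,
                          viscosity = cfg$viscosity)

  prox <- proximity_filter(trajectories, cfg$bead_diameter,
                           cfg$proximity_factor)
  unif <- uniformity_filter(prox$retained, cfg$N)
  records <- unif$retained
  if (length(records) == 0L) stop("no beads survived the pre-filters")

  fits <- lapply(records, function(tr)
    tryCatch(farmas_fit(tr), error = function(e)
      structure(list(bead_id = tr$bead_id, msg = conditionMessage(e)),
                class = "fit_failure")))
  failed <- vapply(fits, inherits, logical(1L), "fit_failure")
  fit_failures <- if (any(failed))
    data.frame(bead_id = vapply(fits[failed], `[[`, character(1L), "bead_id"),
               error = vapply(fits[failed], `[[`, character(1L), "msg"))
  else data.frame(bead_id = character(0L), error = character(0L))
  fits <- fits[!failed]
  if (length(fits) == 0L) stop("every per-bead fit failed")
  tab <- classifier_table(fits, ctx, noise_cutoff = cfg$noise_cutoff)

  groups <- list(); clusters_out <- list(); moduli_out <- list()
  homog_rows <- list()
  omega <- default_omega_grid(cfg$N, cfg$tau, cfg$omega_points)
  cluster_assign <- data.frame(bead_id = tab$bead_id,
                               coarse_label = tab$coarse_label,
                               cluster = NA_integer_)
  for (grp in c("water_like", "flake_like")) {
    in_grp <- which(tab$coarse_label == grp)
    if (length(in_grp) == 0L) next
    gtab <- tab[in_grp, , drop = FALSE]
    hq <- if (length(in_grp) >= 2L)
      .group_homogeneity(gtab, fits, cfg$epsilon) else NULL
    homog_rows[[length(homog_rows) + 1L]] <- data.frame(
      scope = "coarse", group = grp, cluster = NA_integer_,
      n_beads = length(in_grp),
      Q = if (is.null(hq)) NA_real_ else hq$Q,
      df = if (is.null(hq)) NA_integer_ else hq$df,
      p_value = if (is.null(hq)) NA_real_ else hq$p_value,
      reject = if (is.null(hq)) NA else hq$reject,
      low_power = length(in_grp) < 4L)
    heterogeneous <- !is.null(hq) && hq$reject
    if (heterogeneous && length(in_grp) >= 4L) {
      pts <- cbind(alpha = gtab$alpha, logDelta = log(gtab$delta))
      mix <- tryCatch(
        select_model(pts, Kmax = min(cfg$Kmax, floor(length(in_grp) / 2))),
        error = function(e) NULL)
      labs <- if (is.null(mix)) rep(1L, length(in_grp))
              else posterior_assign(mix, pts)$label
    } else {
      mix <- NULL
      labs <- rep(1L, length(in_grp))
    }
    cluster_assign$cluster[in_grp] <- labs
    clusters_out[[grp]] <- mix
    for (k in sort(unique(labs))) {
      sel <- in_grp[labs == k]
      ktab <- tab[sel, , drop = FALSE]
      if (length(sel) >= 2L) {
        hqk <- .group_homogeneity(ktab, fits, cfg$epsilon)
        homog_rows[[length(homog_rows) + 1L]] <- data.frame(
          scope = "cluster", group = grp, cluster = k, n_beads = length(sel),
          Q = if (is.null(hqk)) NA_real_ else hqk$Q,
          df = if (is.null(hqk)) NA_integer_ else hqk$df,
          p_value = if (is.null(hqk)) NA_real_ else hqk$p_value,
          reject = if (is.null(hqk)) NA else hqk$reject,
          low_power = length(sel) < 4L)
      }
      cl_fits <- fits[match(ktab$bead_id,
                            vapply(fits, `[[`, character(1L), "bead_id"))]
      moduli_out[[sprintf("%s_%d", grp, k)]] <- list(
        group = grp, cluster = k, bead_ids = ktab$bead_id,
        gser_average = gser_average(cl_fits, omega, ctx),
        msd_average = msd_average_gser(cl_fits, omega, ctx),
        classifier_average = classifier_average_gser(cl_fits, omega, ctx))
    }
  }

  structure(
    list(classifiers = tab,
         cluster_assignment = cluster_assign,
         homogeneity = if (length(homog_rows)) do.call(rbind, homog_rows)
                       else NULL,
         mixtures = clusters_out,
         moduli = moduli_out,
         filters = list(proximity = prox$exclusions,
                        uniformity = unif$dropped,
                        fit_failures = fit_failures),
         provenance = list(config = unclass(cfg),
                           n_input = length(trajectories),
                           n_retained = length(records),
                           package_version = as.character(
                             utils::packageVersion("pptmstats")),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "protocol_report")
}

#' @export
print.protocol_report <- function(x, ...) {
  cat(sprintf("<protocol_report: %d beads retained of %d>\n",
              x$provenance$n_retained, x$provenance$n_input))
  print(table(x$classifiers$coarse_label))
  invisible(x)
}

#' Write a protocol report's tables to a directory
#'
#' Emits the per-stage CSV tables (classifiers, cluster assignment,
#' homogeneity, moduli curves) and a JSON manifest of the provenance.
#'
#' @param report A `protocol_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "protocol_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$classifiers, file.path(dir, "classifiers.csv"),
            row.names = FALSE)
  write.csv(report$cluster_assignment, file.path(dir, "clusters.csv"),
            row.names = FALSE)
  if (!is.null(report$homogeneity))
    write.csv(report$homogeneity, file.path(dir, "homogeneity.csv"),
              row.names = FALSE)
  mod_rows <- list()
  for (nm in names(report$moduli)) {
    m <- report$moduli[[nm]]
    for (meth in c("gser_average", "msd_average", "classifier_average")) {
      cu <- m[[meth]]
      mod_rows[[length(mod_rows) + 1L]] <- data.frame(
        group = m$group, cluster = m$cluster, method = meth,
        omega = cu$omega, G_storage = cu$G_storage, G_loss = cu$G_loss,
        band_lo_storage = cu$band_lo_storage %||% NA_real_,
        band_hi_storage = cu$band_hi_storage %||% NA_real_,
        band_lo_loss = cu$band_lo_loss %||% NA_real_,
        band_hi_loss = cu$band_hi_loss %||% NA_real_)
    }
  }
  if (length(mod_rows))
    write.csv(do.call(rbind, mod_rows), file.path(dir, "moduli.csv"),
              row.names = FALSE)
  mix_summary <- lapply(report$mixtures, function(m) {
    if (is.null(m)) return(NULL)
    list(K = m$K, constraint = m$constraint, bic = m$bic,
         bic_table = m$bic_table)
  })
  jsonlite::write_json(list(provenance = report$provenance,
                            mixtures = mix_summary),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
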