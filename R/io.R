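# Configuration and trajectory serialization: flat YAML configs, CSV/JSON
# trajectory directories. Everything is plain text.

#' Write / read a parameter set as a flat YAML config
#'
#' Keys are exactly the fields of [model_params()]; absent keys take the
#' defaults, so a config file only needs the values that differ.
#'
#' @param params an `axc_params`.
#' @param path file path.
#' @return `read_params()` returns an `axc_params`; `write_params()` the
#'   path, invisibly.
#' @export
write_params <- function(params, path) {
  p <- unclass(params)
  p$m_max <- if (is.finite(p$m_max)) p$m_max else "unlimited"
  yaml::write_yaml(p, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (identical(raw$m_max, "unlimited")) raw$m_max <- Inf
  do.call(model_params, raw)
}

#' Write / read a scenario as a YAML config
#'
#' Serializes the full scenario — domain, counts, parameters, schedule and
#' run settings — so that users can derive variants by editing the file.
#'
#' @param scenario an `axc_scenario`.
#' @param path file path.
#' @return `read_scenario()` returns an `axc_scenario`; `write_scenario()`
#'   the path, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  sc <- scenario
  p <- unclass(sc$params)
  p$m_max <- if (is.finite(p$m_max)) p$m_max else "unlimited"
  obj <- list(
    name = sc$name,
    domain = list(kind = sc$domain$kind, size = sc$domain$size),
    n_mt = sc$n_mt, n_nf = sc$n_nf,
    params = p,
    schedule = if (is.null(sc$schedule) || !nrow(sc$schedule)) NULL else
      lapply(seq_len(nrow(sc$schedule)), function(i) {
        list(time = sc$schedule$time[i], param = sc$schedule$param[i],
             value = sc$schedule$value[i])
      }),
    t_end = sc$t_end, series_dt = sc$series_dt,
    snapshot_dt = sc$snapshot_dt, randomize_time = sc$randomize_time,
    h_init = sc$h_init, guard = sc$guard
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  if (identical(raw$params$m_max, "unlimited")) raw$params$m_max <- Inf
  dom <- if (raw$domain$kind == "disk") disk_domain(raw$domain$size) else
    periodic_domain(raw$domain$size)
  sched <- NULL
  if (!is.null(raw$schedule)) {
    sched <- event_schedule(
      vapply(raw$schedule, `[[`, numeric(1), "time"),
      vapply(raw$schedule, `[[`, character(1), "param"),
      vapply(raw$schedule, `[[`, numeric(1), "value")
    )
  }
  structure(list(
    name = raw$name, domain = dom, n_mt = raw$n_mt, n_nf = raw$n_nf,
    params = do.call(model_params, raw$params), schedule = sched,
    t_end = raw$t_end, series_dt = raw$series_dt,
    snapshot_dt = raw$snapshot_dt, randomize_time = raw$randomize_time,
    h_init = raw$h_init, guard = isTRUE(raw$guard)
  ), class = "axc_scenario")
}

# flatten one snapshot into a tidy particle table
.snapshot_df <- function(t, state, bonds) {
  n_mt <- nrow(state$mt); n_nf <- nrow(state$nf); n_org <- nrow(state$org)
  org_rad <- if (n_org) {
    organelle_radius(state$org$z, state$org$a, state$org$b)
  } else numeric(0)
  df <- data.frame(
    t = t,
    type = c(rep("MT", n_mt), rep("NF", n_nf), rep("ORG", n_org)),
    id = c(seq_len(n_mt), seq_len(n_nf), seq_len(n_org)),
    x = c(state$mt[, 1], state$nf[, 1], state$org$x),
    y = c(state$mt[, 2], state$nf[, 2], state$org$y),
    z = c(rep(NA_real_, n_mt + n_nf), state$org$z),
    a = c(rep(NA_real_, n_mt + n_nf), state$org$a),
    b = c(rep(NA_real_, n_mt + n_nf), state$org$b),
    radius = c(rep(state$mt_radius, n_mt), rep(state$nf_radius, n_nf),
               org_rad),
    bonds = c(rep(NA_character_, n_mt),
              ifelse(is.na(bonds$nf), "", as.character(bonds$nf)),
              vapply(bonds$org, paste, character(1), collapse = ";"))
  )
  df
}

.df_snapshot <- function(df, domain) {
  mt <- df[df$type == "MT", ]
  nf <- df[df$type == "NF", ]
  og <- df[df$type == "ORG", ]
  state <- particle_state(
    mt = cbind(mt$x, mt$y), nf = cbind(nf$x, nf$y),
    org = data.frame(x = as.numeric(og$x), y = as.numeric(og$y),
                     z = as.numeric(og$z), a = as.numeric(og$a),
                     b = as.numeric(og$b)),
    domain = domain,
    mt_radius = if (nrow(mt)) mt$radius[1] else 12.5,
    nf_radius = if (nrow(nf)) nf$radius[1] else 5
  )
  nfb <- suppressWarnings(as.integer(nf$bonds))
  orgb <- lapply(og$bonds, function(s) {
    if (is.na(s) || !nzchar(s)) integer(0) else
      as.integer(strsplit(s, ";")[[1]])
  })
  bonds <- structure(list(nf = nfb, org = orgb), class = "axc_bonds")
  list(state = state, bonds = bonds)
}

#' Write / read a trajectory directory
#'
#' A trajectory is stored as plain text: `meta.json` (domain, parameters,
#' schedule, seed — enough to re-run the simulation identically),
#' `series.csv` (the summary series), and one `snapshot_NNN.csv` per
#' stored configuration.
#'
#' @param traj an `axc_trajectory`.
#' @param dir directory (created if needed).
#' @return `read_trajectory()` returns an `axc_trajectory` (without
#'   counters); `write_trajectory()` the directory, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- unclass(traj$params)
  p$m_max <- if (is.finite(p$m_max)) p$m_max else "unlimited"
  meta <- list(
    package_version = as.character(utils::packageVersion("axoncross")),
    seed = traj$seed,
    t_final = traj$t_final,
    domain = list(kind = traj$final_state$domain$kind,
                  size = traj$final_state$domain$size),
    params = p,
    schedule = if (is.null(traj$schedule) || !nrow(traj$schedule)) NULL else
      as.data.frame(traj$schedule),
    counters = as.list(traj$counters)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write.csv(traj$series, file.path(dir, "series.csv"), row.names = FALSE)
  for (i in seq_along(traj$snapshots)) {
    s <- traj$snapshots[[i]]
    write.csv(.snapshot_df(s$t, s$state, s$bonds),
              file.path(dir, sprintf("snapshot_%04d.csv", i)),
              row.names = FALSE)
  }
  write.csv(.snapshot_df(traj$t_final, traj$final_state, traj$final_bonds),
            file.path(dir, "final.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  dom <- if (meta$domain$kind == "disk") disk_domain(meta$domain$size) else
    periodic_domain(meta$domain$size)
  pl <- meta$params
  if (identical(pl$m_max, "unlimited")) pl$m_max <- Inf
  params <- do.call(model_params, pl)
  series <- read.csv(file.path(dir, "series.csv"))
  snap_files <- sort(list.files(dir, "^snapshot_[0-9]+\\.csv$",
                                full.names = TRUE))
  snaps <- lapply(snap_files, function(f) {
    df <- read.csv(f, colClasses = list(bonds = "character"))
    sb <- .df_snapshot(df, dom)
    list(t = df$t[1], state = sb$state, bonds = sb$bonds)
  })
  fin <- .df_snapshot(read.csv(file.path(dir, "final.csv"),
                               colClasses = list(bonds = "character")), dom)
  sched <- NULL
  if (!is.null(meta$schedule)) {
    sched <- event_schedule(meta$schedule$time, meta$schedule$param,
                            meta$schedule$value)
  }
  structure(list(
    series = series, snapshots = snaps, final_state = fin$state,
    final_bonds = fin$bonds, t_final = meta$t_final,
    counters = unlist(meta$counters), params = params, schedule = sched,
    seed = meta$seed
  ), class = "axc_trajectory")
}
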