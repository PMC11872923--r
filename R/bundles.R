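# Directory-of-CSV bundle IO: movies as one CSV per channel plus JSON
# metadata; sweep sets as time/voltage columns plus a JSON event table.

#' Write a line-scan movie bundle
#' @param movie A [linescan_movie()].
#' @param dir Output directory (created).
#' @export
write_linescan_bundle <- function(movie, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(movie$green, file.path(dir, "green.csv"), row.names = FALSE)
  utils::write.csv(movie$red, file.path(dir, "red.csv"), row.names = FALSE)
  meta <- movie[setdiff(names(movie), c("green", "red"))]
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a line-scan movie bundle
#' @param dir Bundle directory from [write_linescan_bundle()].
#' @export
read_linescan_bundle <- function(dir) {
  g <- as.matrix(utils::read.csv(file.path(dir, "green.csv")))
  r <- as.matrix(utils::read.csv(file.path(dir, "red.csv")))
  dimnames(g) <- dimnames(r) <- NULL
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  linescan_movie(g, r, meta$ms_per_line, meta$pixels_per_um, meta$stim_onset,
                 distance_to_soma = meta$distance_to_soma %||% NA_real_,
                 depth = meta$depth %||% NA_real_,
                 state = meta$state %||% "rest",
                 roi = meta$roi, background = meta$background)
}

#' Write a sweep set bundle (one trace CSV per sweep + JSON metadata)
#' @param sweeps List of [cc_sweep()]s.
#' @param dir Output directory.
#' @export
write_sweep_bundle <- function(sweeps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- lapply(seq_along(sweeps), function(i) {
    sw <- sweeps[[i]]
    utils::write.csv(data.frame(voltage = sw$voltage),
                     file.path(dir, sprintf("sweep_%04d.csv", i)),
                     row.names = FALSE)
    list(sample_rate = sw$sample_rate, temperature = sw$temperature,
         sweep_time = sw$sweep_time, events = sw$events)
  })
  jsonlite::write_json(meta, file.path(dir, "sweeps.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a sweep set bundle
#' @param dir Bundle directory from [write_sweep_bundle()].
#' @export
read_sweep_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "sweeps.json"), simplifyVector = TRUE)
  lapply(seq_len(nrow(meta)), function(i) {
    v <- utils::read.csv(file.path(dir, sprintf("sweep_%04d.csv", i)))$voltage
    ev <- meta$events[[i]]
    cc_sweep(v, meta$sample_rate[i],
             events = if (is.data.frame(ev)) ev else NULL,
             temperature = meta$temperature[i], sweep_time = meta$sweep_time[i])
  })
}
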