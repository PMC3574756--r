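#' Write a run's trajectory, distributions and manifest to a directory
#'
#' Writes `trajectory.tsv` (tab-separated, '.' decimal), a
#' `manifest.json` run manifest (configuration echo, seed if any, package
#' version) and optionally per-generation distribution dumps under
#' `distributions/` (only generations retained by the run's `keep`
#' setting are dumped).
#'
#' @param run a `gw_run`.
#' @param out_dir output directory (created if missing).
#' @param dump_distributions also write retained distributions as TSV.
#' @param seed optional seed to echo into the manifest.
#' @return `out_dir`, invisibly.
#' @export
write_trajectory <- function(run, out_dir, dump_distributions = FALSE,
                             seed = NULL) {
  stopifnot(inherits(run, "gw_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_traj_tsv(run$trajectory, file.path(out_dir, "trajectory.tsv"))
  manifest <- list(
    kind = run$kind,
    generations = run$generations,
    seed = seed,
    package_version = as.character(utils::packageVersion("gwimmune")),
    config = config_echo(run$params))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (dump_distributions && !is.null(run$distributions)) {
    ddir <- file.path(out_dir, "distributions")
    dir.create(ddir, showWarnings = FALSE)
    for (i in seq_along(run$distributions)) {
      d <- run$distributions[[i]]
      if (inherits(d, "gw_dist")) {
        write_dist_tsv(d, file.path(ddir, sprintf("state_%04d.tsv", i - 1L)))
      } else {
        for (nm in names(d)) {
          write_dist_tsv(d[[nm]], file.path(
            ddir, sprintf("%s_%04d.tsv", nm, i - 1L)))
        }
      }
    }
  }
  invisible(out_dir)
}

write_traj_tsv <- function(traj, path) {
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# flatten a parameter object into plain lists for the JSON manifest
config_echo <- function(x) {
  if (inherits(x, "gw_maturation_schedule")) {
    return(list(phases = lapply(x$phases, function(p)
      list(from = p$from, params = config_echo(p$params)))))
  }
  if (is.list(x)) {
    out <- lapply(unclass(x), config_echo)
    return(out)
  }
  x
}

#' Read a trajectory TSV written by [write_trajectory()]
#'
#' @param path path to a `trajectory.tsv`.
#' @return a tibble.
#' @export
read_trajectory <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}
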