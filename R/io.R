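# Plain-text I/O for trajectory collections and run configuration.

#' Write trajectories to CSV (with optional JSON manifest)
#'
#' Long-format CSV with columns `molecule_id, time_s, I_D, I_A`. Truth
#' annotations and simulation settings, when present, go to a sidecar JSON
#' manifest next to the CSV.
#'
#' @param trajs List of `molecule_trajectory` objects (named).
#' @param path Output CSV path.
#' @param manifest Write `<path>.json` with settings and truth tables
#'   (default TRUE).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path, manifest = TRUE) {
  stopifnot(length(trajs) >= 1L)
  ids <- names(trajs)
  if (is.null(ids)) ids <- sprintf("mol%05d", seq_along(trajs))
  tab <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    data.frame(molecule_id = ids[i], time_s = tr$times,
               I_D = tr$I_D, I_A = tr$I_A)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  if (manifest) {
    man <- list(
      settings = attr(trajs, "manifest"),
      truth = stats::setNames(lapply(trajs, function(tr) tr$truth), ids)
    )
    jsonlite::write_json(man, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read trajectories from CSV
#'
#' Inverse of [write_trajectories()]. Truth annotations are restored from the
#' sidecar manifest when present.
#'
#' @param path CSV path with columns `molecule_id, time_s, I_D, I_A`.
#' @return Named list of `molecule_trajectory` objects.
#' @export
read_trajectories <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("molecule_id", "time_s", "I_D", "I_A")
  if (!all(need %in% names(tab)))
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  man_path <- paste0(path, ".json")
  truth_tabs <- NULL
  if (file.exists(man_path)) {
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    truth_tabs <- man$truth
  }
  ids <- unique(tab$molecule_id)
  trajs <- lapply(ids, function(id) {
    sub <- tab[tab$molecule_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_s), , drop = FALSE]
    truth <- if (!is.null(truth_tabs) && !is.null(truth_tabs[[id]]) &&
                 length(truth_tabs[[id]])) {
      as.data.frame(truth_tabs[[id]])
    } else .empty_truth()
    structure(list(times = sub$time_s, I_D = sub$I_D, I_A = sub$I_A,
                   truth = truth),
              class = "molecule_trajectory")
  })
  stats::setNames(trajs, ids)
}

#' Read a flat key/value run-configuration file
#'
#' Parses `key = value` lines (TOML-like flat table; `#` comments allowed) and
#' returns a [field_spec()] plus any extra keys.
#'
#' @param path Configuration file path.
#' @return List with elements `field` (a `field_spec`) and `extra`.
#' @export
read_field_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", lines))
  kv <- kv[lengths(kv) == 3L]
  vals <- stats::setNames(lapply(kv, function(m) {
    v <- gsub('^"|"$', "", trimws(m[[3L]]))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }), vapply(kv, `[[`, "", 2L))
  known <- c("n_molecules", "dt", "duration", "power_scale", "seed")
  args <- vals[intersect(names(vals), known)]
  list(field = do.call(field_spec, args),
       extra = vals[setdiff(names(vals), known)])
}
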