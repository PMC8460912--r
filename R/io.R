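# Plain-text interchange: liquid/gas series CSV, event log JSON, count TSV.

#' Write and read liquid concentration series
#'
#' CSV with a `time_d` column and one column per compound with a unit suffix
#' (`<compound>_mM`). Reading converts any `<compound>_gL` column to mM via
#' the registry.
#'
#' @param series Data frame (`time_d` + concentration columns).
#' @param path File path.
#' @return `read_liquid_csv()` returns a data frame with `time_d` and
#'   bare-named mM columns.
#' @export
write_liquid_csv <- function(series, path) {
  out <- series
  cols <- setdiff(names(out), "time_d")
  plain <- !grepl("_(mM|gL)$", cols)
  names(out)[match(cols[plain], names(out))] <- paste0(cols[plain], "_mM")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_liquid_csv
#' @param registry Registry data frame (for g/L conversion).
#' @export
read_liquid_csv <- function(path, registry = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  stopifnot("time_d" %in% names(d))
  out <- data.frame(time_d = d$time_d)
  for (cn in setdiff(names(d), "time_d")) {
    if (grepl("_gL$", cn)) {
      nm <- sub("_gL$", "", cn)
      out[[nm]] <- mass_to_molar(d[[cn]], nm, registry)
    } else {
      out[[sub("_mM$", "", cn)]] <- d[[cn]]
    }
  }
  out
}

#' Write and read gas-phase series
#'
#' CSV with `time_d`, fraction columns `y_<species>`, and optionally
#' `v_gas_ml`.
#'
#' @param gas Data frame.
#' @param path File path.
#' @export
write_gas_csv <- function(gas, path) {
  utils::write.csv(gas, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gas_csv
#' @export
read_gas_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  stopifnot("time_d" %in% names(d), any(grepl("^y_", names(d))))
  d
}

#' Write and read the gas event log
#'
#' JSON list of events `{time_d, type, volumes_ml: {species: mL}}`.
#'
#' @param events Event data frame as produced by [simulate_reactor()]
#'   (columns `time_d`, `type`, `vol_<species>_ml`).
#' @param path File path.
#' @export
write_events_json <- function(events, path) {
  vcols <- grep("^vol_.*_ml$", names(events), value = TRUE)
  species <- sub("^vol_", "", sub("_ml$", "", vcols))
  lst <- lapply(seq_len(nrow(events)), function(i) {
    vols <- as.list(setNames(as.numeric(events[i, vcols]), species))
    list(time_d = events$time_d[i], type = events$type[i],
         volumes_ml = vols[unlist(vols) != 0])
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_events_json
#' @export
read_events_json <- function(path) {
  lst <- jsonlite::read_json(path)
  species <- unique(unlist(lapply(lst, function(e) names(e$volumes_ml))))
  rows <- lapply(lst, function(e) {
    v <- setNames(rep(0, length(species)), species)
    v[names(e$volumes_ml)] <- unlist(e$volumes_ml)
    cbind(data.frame(time_d = e$time_d, type = e$type),
          as.data.frame(as.list(setNames(v, paste0("vol_", species, "_ml")))))
  })
  do.call(rbind, rows)
}

#' Write and read a genus count table
#'
#' TSV with samples as rows (first column `sample_id`) and taxa as columns.
#'
#' @param counts Samples x taxa matrix.
#' @param path File path.
#' @export
write_counts_tsv <- function(counts, path) {
  d <- data.frame(sample_id = rownames(counts) %||%
                    paste0("s", seq_len(nrow(counts))),
                  as.data.frame(unclass(counts), check.names = FALSE),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}
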