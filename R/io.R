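# CSV persistence for simulated objects. Observable columns go to the main
# CSV; latent truth (true rates, petite flags, lineage identity) goes to a
# "<stem>_latent.csv" sidecar so that analysis code reading the observable
# file cannot accidentally consume it.

POP_LATENT_COLS <- c("true_rate", "lag", "is_petite")
POP_REQUIRED_COLS <- c("colony_id", "strain", "plate", "well", "field",
                       "centroid_x", "centroid_y", "mito_intensity",
                       "reporter_intensity")
CELLS_REQUIRED_COLS <- c("cell_id", "t_min", "nuc_median", "cyt_median",
                         "bbox_bg_median")

#' Write simulated tables to CSV (latent truth in a sidecar)
#'
#' @param x A `microhet_population`, `msn2_cells` or `heatshock_phases`
#'   object.
#' @param path Output stem: files are written as `<path>.csv` plus
#'   `<path>_latent.csv` (and `<path>_pre/post.csv` for heat-shock phases).
#' @return Invisibly, the character vector of files written.
#' @seealso [read_tables()]
#' @export
write_tables <- function(x, path) UseMethod("write_tables")

#' @export
write_tables.microhet_population <- function(x, path) {
  x <- as_tibble(x)
  latent <- x[, c("colony_id", intersect(POP_LATENT_COLS, names(x)))]
  obs <- x[, setdiff(names(x), POP_LATENT_COLS)]
  files <- c(paste0(path, ".csv"), paste0(path, "_latent.csv"))
  readr::write_csv(obs, files[1])
  readr::write_csv(latent, files[2])
  invisible(files)
}

#' @export
write_tables.msn2_cells <- function(x, path) {
  files <- c(paste0(path, ".csv"), paste0(path, "_latent.csv"))
  readr::write_csv(x$cells, files[1])
  readr::write_csv(x$latent, files[2])
  invisible(files)
}

#' @export
write_tables.heatshock_phases <- function(x, path) {
  files <- c(paste0(path, "_pre.csv"), paste0(path, "_post.csv"),
             paste0(path, "_latent.csv"))
  readr::write_csv(x$pre, files[1])
  readr::write_csv(x$post, files[2])
  readr::write_csv(x$latent, files[3])
  invisible(files)
}

#' Read tables written by [write_tables()]
#'
#' Validates the schema (a missing required column is an error naming the
#' column); unknown extra columns are preserved untouched. The latent sidecar
#' is read only when present.
#'
#' @param path The stem passed to [write_tables()].
#' @param kind `"population"`, `"msn2"`, or `"heatshock"`.
#' @return The corresponding object; for `"population"` the latent columns
#'   are re-joined when the sidecar exists.
#' @export
read_tables <- function(path, kind = c("population", "msn2", "heatshock")) {
  kind <- match.arg(kind)
  switch(kind,
    population = read_population(path),
    msn2 = read_msn2(path),
    heatshock = read_heatshock(path)
  )
}

read_csv_checked <- function(file, required) {
  if (!file.exists(file)) abort(sprintf("file not found: %s", file))
  x <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s",
                  basename(file), paste(missing, collapse = ", ")))
  }
  x
}

read_population <- function(path) {
  obs <- read_csv_checked(paste0(path, ".csv"), POP_REQUIRED_COLS)
  if (!any(grepl("^area_h[0-9]+$", names(obs)))) {
    abort(sprintf("%s.csv: missing area series columns (area_h<t>)",
                  basename(path)))
  }
  sidecar <- paste0(path, "_latent.csv")
  if (file.exists(sidecar)) {
    latent <- read_csv_checked(sidecar, "colony_id")
    obs <- dplyr::left_join(obs, latent, by = "colony_id")
  }
  class(obs) <- c("microhet_population", class(obs))
  obs
}

read_msn2 <- function(path) {
  cells <- read_csv_checked(paste0(path, ".csv"), CELLS_REQUIRED_COLS)
  sidecar <- paste0(path, "_latent.csv")
  latent <- if (file.exists(sidecar)) {
    read_csv_checked(sidecar, c("cell_id", "true_rate"))
  } else NULL
  structure(list(cells = cells, latent = latent), class = "msn2_cells")
}

read_heatshock <- function(path) {
  pre <- read_csv_checked(paste0(path, "_pre.csv"),
                          c("colony_id", "centroid_x", "centroid_y"))
  post <- read_csv_checked(paste0(path, "_post.csv"),
                           c("colony_id", "centroid_x", "centroid_y"))
  sidecar <- paste0(path, "_latent.csv")
  latent <- if (file.exists(sidecar)) {
    read_csv_checked(sidecar, c("pre_id", "post_id", "alive"))
  } else NULL
  structure(list(pre = pre, post = post, latent = latent),
            class = "heatshock_phases")
}
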