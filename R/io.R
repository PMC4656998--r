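#' Read field geometry from WKT, GeoJSON or CSV
#'
#' Accepted formats, decided by file extension (or content for `.txt`):
#' * `.wkt` / `.txt`: a single `POLYGON ((x y, ...))` in metre coordinates;
#' * `.geojson` / `.json`: a GeoJSON `Polygon` (or a Feature holding one);
#' * `.csv`: one row with columns `area_m2` and `perimeter_m`.
#'
#' @param path file path.
#' @return a [field_geometry()].
#' @export
load_geometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("wkt", "txt")) {
    field_geometry(polygon = parse_wkt_polygon(paste(readLines(path, warn = FALSE),
                                                     collapse = " ")))
  } else if (ext %in% c("geojson", "json")) {
    field_geometry(polygon = parse_geojson_polygon(jsonlite::read_json(path)))
  } else if (ext == "csv") {
    df <- utils::read.csv(path)
    need <- c("area_m2", "perimeter_m")
    if (!all(need %in% names(df))) {
      stop("geometry CSV must have columns area_m2, perimeter_m")
    }
    if (nrow(df) < 1) stop("empty input file: ", path)
    field_geometry(df$area_m2[1], df$perimeter_m[1])
  } else {
    stop("unsupported geometry format: .", ext)
  }
}

#' Parse a WKT POLYGON string
#'
#' Supports a single `POLYGON` with one outer ring (no holes), planar
#' metre coordinates, dot decimal separator.
#'
#' @param text WKT string.
#' @return two-column coordinate matrix.
#' @export
parse_wkt_polygon <- function(text) {
  text <- trimws(text)
  if (!grepl("^POLYGON", text, ignore.case = TRUE)) {
    stop("not a WKT POLYGON: ", substr(text, 1, 40))
  }
  inner <- regmatches(text, regexpr("\\(\\s*\\([^)]*\\)", text))
  if (length(inner) == 0) stop("malformed WKT POLYGON: no coordinate ring found")
  coords <- gsub("[()]", "", inner)
  pairs <- strsplit(trimws(strsplit(coords, ",")[[1]]), "\\s+")
  bad <- which(lengths(pairs) != 2)
  if (length(bad) > 0) stop("malformed WKT coordinate pair at position ", bad[1])
  m <- do.call(rbind, lapply(pairs, as.numeric))
  if (anyNA(m)) stop("non-numeric WKT coordinates")
  m
}

parse_geojson_polygon <- function(gj) {
  if (!is.null(gj$type) && gj$type == "Feature") gj <- gj$geometry
  if (is.null(gj$type) || gj$type != "Polygon") {
    stop("GeoJSON must contain a single Polygon")
  }
  ring <- gj$coordinates[[1]]
  m <- do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt)[1:2])))
  if (anyNA(m)) stop("non-numeric GeoJSON coordinates")
  m
}

#' Write a sample sheet, read measurements back
#'
#' A [sample_set] is stored as plain CSV with its layout columns plus the
#' design name and the field summaries; `load_samples()` restores the
#' object (measured or not).  Writing a design, sending it to the field,
#' and reading the filled sheet back round-trips exactly.
#'
#' @param ss a [sample_set].
#' @param path CSV path.
#' @return `write_samples()` returns `path` invisibly; `load_samples()`
#'   returns a [sample_set].
#' @export
write_samples <- function(ss, path) {
  stopifnot(inherits(ss, "sample_set"))
  geom <- attr(ss, "geom")
  df <- as.data.frame(ss)
  df$design <- attr(ss, "design")
  df$area_m2 <- geom$area_m2
  df$perimeter_m <- geom$perimeter_m
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
load_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  df <- utils::read.csv(path)
  need <- c("id", "role", "arm", "transect", "side", "x", "y", "depth_d",
            "n_cobs", "value_pct", "design", "area_m2", "perimeter_m")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("sample CSV missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop("empty input file: ", path)
  geom <- field_geometry(df$area_m2[1], df$perimeter_m[1])
  design <- df$design[1]
  for (col in c("x", "y", "depth_d", "value_pct")) {
    if (!is.numeric(df[[col]])) stop("non-numeric values in column ", col)
  }
  new_sample_set(df[, setdiff(need, c("design", "area_m2", "perimeter_m"))],
                 design, geom)
}

#' Write a report object as JSON
#'
#' Serialises estimates, decision reports or any list-like result to JSON,
#' stamped with the package version so that regulatory outputs are
#' traceable.
#'
#' @param obj object to serialise (`gm_estimate`, `decision_report`, list, ...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(obj, path) {
  payload <- list(
    package = "gmflow",
    version = as.character(utils::packageVersion("gmflow")),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    report = unclass_deep(obj))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    attributes(x) <- attributes(x)["names"]
    x
  }
}

#' Read a simulator configuration from YAML
#'
#' The YAML file mirrors the arguments of [simulation_config()]; geometry
#' is given inline as `area_m2`/`perimeter_m` or as a `polygon` list of
#' `[x, y]` pairs.
#'
#' @param path YAML path.
#' @return a [simulation_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  geom <- if (!is.null(y$polygon)) {
    field_geometry(polygon = do.call(rbind, lapply(y$polygon, as.numeric)))
  } else {
    field_geometry(y$area_m2, y$perimeter_m)
  }
  args <- y[setdiff(names(y), c("area_m2", "perimeter_m", "polygon"))]
  if (!is.null(args$side_V0)) args$side_V0 <- as.numeric(unlist(args$side_V0))
  do.call(simulation_config, c(list(geometry = geom), args))
}

#' Packaged field survey table
#'
#' Loads the packaged 19-field survey compilation (five seasons of paired
#' standard/simplified monitoring): per field the area, Self-Protection
#' Index, sampling depth, periphery and centre analyses, and the published
#' whole-field estimates.  Values printed below the 0.01% detection limit
#' are stored as 0 with `below_lod = TRUE`.  The `note` column marks rows
#' whose published estimates cannot be recomputed from the tabulated
#' periphery values (the published numbers came from the pooled-sample
#' qPCR reading rather than the tabulated per-sample means).
#'
#' @return data frame with 19 rows.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "survey_fields.csv", package = "gmflow")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
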