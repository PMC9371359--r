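# Parameter configs are written as plain YAML (canonical) or JSON mirrors of
# the cea_parameters structure. The schema is explicit and versioned: unknown
# keys, missing keys and non-numeric values are errors, never warnings, since
# a silently dropped or misspelled parameter corrupts every downstream result.

INTEGER_FIELDS <- c("schema_version", "horizon_cycles")

to_plain <- function(x) {
  if (is.data.frame(x)) x <- as.list(x)
  if (is.list(x)) return(lapply(x, to_plain))
  if (is.numeric(x)) {
    x <- unname(x)
    if (any(is.infinite(x))) return(lapply(x, function(v)
      if (is.infinite(v)) "Inf" else v))
  }
  x
}

coerce_num <- function(x, where) {
  x <- unlist(x, use.names = FALSE)
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !(is.na(x) | x %in% c("NA", ".na"))
  if (any(bad))
    stop("config: non-numeric value ", deparse(x[bad][1]), " at key '", where, "'")
  out
}

#' Write a parameter set to a YAML or JSON config file
#'
#' @param ps A [cea_parameters()] set.
#' @param path Output path; the extension (`.yaml`/`.yml` or `.json`) selects
#'   the format.
#' @return `path`, invisibly.
#' @seealso [read_parameters()]
#' @export
write_parameters <- function(ps, path) {
  stopifnot(inherits(ps, "cea_parameters"))
  plain <- to_plain(unclass(ps))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    writeLines(yaml::as.yaml(plain, precision = 12L), path)
  } else if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "string", pretty = TRUE)
  } else {
    stop("unsupported config extension: '", ext, "' (use yaml, yml or json)")
  }
  invisible(path)
}

#' Read a parameter set from a YAML or JSON config file
#'
#' The file must follow the shipped schema exactly: every key of the parameter
#' inventory present, no unknown keys, every value numeric where a number is
#' expected. The loaded set must additionally pass [validate_parameters()]
#' with no violations. Round trips through [write_parameters()] are
#' value-identical.
#'
#' @param path Path to a config produced by [write_parameters()] (or written
#'   by hand to the same schema).
#' @return A validated [cea_parameters()] set.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop("unsupported config extension: '", ext, "'")
  }
  skeleton <- unclass(cea_parameters())
  ps <- from_plain(raw, skeleton, where = "")
  class(ps) <- "cea_parameters"
  viol <- validate_parameters(ps)
  if (length(viol))
    stop("config fails validation:\n  - ", paste(viol, collapse = "\n  - "))
  ps
}

from_plain <- function(raw, skel, where) {
  if (is.data.frame(skel)) {
    cols <- setdiff(names(skel), character(0))
    check_keys(raw, cols, where)
    out <- skel
    n <- nrow(skel)
    for (cl in cols) {
      val <- if (cl %in% c("id")) as.character(unlist(raw[[cl]]))
             else coerce_num(raw[[cl]], paste0(where, ".", cl))
      if (length(val) != n)
        stop("config: key '", where, ".", cl, "' must have ", n, " values")
      if (is.integer(skel[[cl]])) val <- as.integer(val)
      out[[cl]] <- val
    }
    return(out)
  }
  if (is.list(skel)) {
    check_keys(raw, names(skel), where,
               optional = if (where == ".effects") "lambda1_override")
    out <- skel
    for (nm in names(skel))
      out[[nm]] <- from_plain(raw[[nm]], skel[[nm]],
                              paste0(where, ".", nm))
    if (!is.null(raw$lambda1_override) && where == ".effects")
      out$lambda1_override <- lapply(raw$lambda1_override, coerce_num,
                                     where = paste0(where, ".lambda1_override"))
    return(out)
  }
  if (is.character(skel)) {
    val <- unlist(raw, use.names = FALSE)
    if (!is.character(val) || length(val) != length(skel))
      stop("config: key '", where, "' must be a string")
    return(val)
  }
  if (is.logical(skel)) {
    val <- unlist(raw, use.names = FALSE)
    if (!is.logical(val) || length(val) != length(skel))
      stop("config: key '", where, "' must be true/false")
    return(val)
  }
  val <- coerce_num(raw, where)
  if (length(val) != length(skel))
    stop("config: key '", where, "' must have ", length(skel), " value(s)")
  leaf <- sub(".*\\.", "", where)
  if (leaf %in% INTEGER_FIELDS) val <- as.integer(val)
  if (!is.null(names(skel))) names(val) <- names(skel)
  val
}

check_keys <- function(raw, expected, where, optional = character(0)) {
  if (!is.list(raw))
    stop("config: expected a mapping at key '", if (nzchar(where)) where else "<root>", "'")
  got <- names(raw)
  unknown <- setdiff(got, c(expected, optional))
  missing <- setdiff(expected, got)
  if (length(unknown))
    stop("config: unknown key '", paste0(where, ".", unknown[1]), "'")
  if (length(missing))
    stop("config: missing key '", paste0(where, ".", missing[1]), "'")
}

#' Write the published base-case parameter config
#'
#' Emits the full default parameter inventory as a machine-readable config.
#' The shipped copy of this fixture lives at
#' `system.file("extdata", "parameters.yaml", package = "exeCEA")`.
#'
#' @param path Output path (YAML or JSON).
#' @return `path`, invisibly.
#' @export
write_default_config <- function(path) {
  write_parameters(cea_parameters(), path)
}
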