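#' Construct an information system
#'
#' An information system is the rough-set formalism's table of objects by
#' attributes: a numeric value matrix with unique object labels, an ordered
#' attribute set, and optionally designated decision (stage), follow-up-time
#' and event columns.  All pipeline stages consume and produce this
#' container.
#'
#' @param values Numeric matrix or data frame, objects in rows and
#'   attributes in columns.  Column names are the attribute names.
#' @param object_ids Character vector of unique object labels; defaults to
#'   the row names of `values` or `o1..on`.
#' @param decision Name of the decision attribute (ordinal stage), or `NULL`.
#' @param time Name of the follow-up-time attribute (months), or `NULL`.
#' @param event Name of the 0/1 event-indicator attribute, or `NULL`.
#' @param categorical Character vector of attribute names to treat as
#'   categorical (excluded from fuzzy proximity and regression designs).
#' @return An object of class `information_system` with elements `values`
#'   (numeric matrix), `object_ids`, `attributes` (data frame of name and
#'   kind), and the decision/time/event role names.
#' @examples
#' is1 <- information_system(
#'   matrix(1:6, 2, 3, dimnames = list(c("P1", "P2"), c("a1", "a2", "d"))),
#'   decision = "d")
#' is1$attributes
#' @export
information_system <- function(values, object_ids = NULL, decision = NULL,
                               time = NULL, event = NULL,
                               categorical = character()) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (non-numeric cells are an error)",
         call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("information system must have at least one object and one attribute",
         call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("a", seq_len(ncol(values)))
  if (is.null(object_ids)) {
    object_ids <- rownames(values)
    if (is.null(object_ids)) object_ids <- paste0("o", seq_len(nrow(values)))
  }
  object_ids <- as.character(object_ids)
  if (length(object_ids) != nrow(values))
    stop("length(object_ids) must equal nrow(values)", call. = FALSE)
  if (anyDuplicated(object_ids))
    stop("duplicate object ids: ",
         paste(unique(object_ids[duplicated(object_ids)]), collapse = ", "),
         call. = FALSE)
  rownames(values) <- object_ids

  nm <- colnames(values)
  roles <- list(decision = decision, time = time, event = event)
  for (r in names(roles)) {
    if (!is.null(roles[[r]]) && !roles[[r]] %in% nm)
      stop(sprintf("%s attribute '%s' not found among attributes",
                   r, roles[[r]]), call. = FALSE)
  }
  set_roles <- unlist(roles)
  if (anyDuplicated(set_roles))
    stop("decision/time/event attributes must be distinct", call. = FALSE)
  bad <- setdiff(categorical, nm)
  if (length(bad))
    stop("unknown categorical attribute(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  kind <- rep("numeric", length(nm))
  kind[nm %in% categorical] <- "categorical"
  if (!is.null(decision)) kind[nm == decision] <- "decision"
  if (!is.null(time))     kind[nm == time]     <- "time"
  if (!is.null(event))    kind[nm == event]    <- "event"

  structure(
    list(values = values,
         object_ids = object_ids,
         attributes = data.frame(name = nm, kind = kind,
                                 stringsAsFactors = FALSE),
         decision_attribute = decision,
         time_attribute = time,
         event_attribute = event),
    class = "information_system")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.information_system <- function(x, ...) {
  cat(sprintf("information system: %d objects x %d attributes\n",
              nrow(x$values), ncol(x$values)))
  roles <- c(decision = x$decision_attribute %||% "<none>",
             time = x$time_attribute %||% "<none>",
             event = x$event_attribute %||% "<none>")
  cat(sprintf("  decision: %s  time: %s  event: %s\n",
              roles[1], roles[2], roles[3]))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' @export
as.data.frame.information_system <- function(x, ...) {
  as.data.frame(x$values)
}

#' Names of the conditional attributes
#'
#' @param is An `information_system`.
#' @param kinds Attribute kinds to keep (default both numeric and
#'   categorical conditionals).
#' @return Character vector of attribute names, excluding the decision,
#'   time and event attributes unless their kinds are requested.
#' @export
conditional_attributes <- function(is, kinds = c("numeric", "categorical")) {
  stopifnot(inherits(is, "information_system"))
  is$attributes$name[is$attributes$kind %in% kinds]
}

#' Read an information system from CSV
#'
#' The CSV dialect is comma-separated, UTF-8, `.` decimal, with a required
#' header row.  The first column may hold object labels (named `object`, or
#' any non-numeric first column); every remaining cell must be numeric.
#'
#' @param path Path to a CSV file.
#' @inheritParams information_system
#' @param id_column Name of the object-label column, or `NULL` to
#'   auto-detect (`object` or a non-numeric first column).
#' @return An `information_system`.
#' @export
read_information_system <- function(path, decision = NULL, time = NULL,
                                    event = NULL, categorical = character(),
                                    id_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) stop("schema error reading '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop("schema error: '", path, "' has no data rows", call. = FALSE)

  if (is.null(id_column)) {
    if ("object" %in% names(df)) id_column <- "object"
    else if (!is.numeric(df[[1]])) id_column <- names(df)[1]
  }
  if (!is.null(id_column)) {
    if (!id_column %in% names(df))
      stop("schema error: id column '", id_column, "' missing", call. = FALSE)
    ids <- as.character(df[[id_column]])
    df[[id_column]] <- NULL
  } else {
    ids <- paste0("o", seq_len(nrow(df)))
  }
  non_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(non_num))
    stop("non-numeric cells in column(s): ", paste(non_num, collapse = ", "),
         call. = FALSE)
  information_system(as.matrix(df), object_ids = ids, decision = decision,
                     time = time, event = event, categorical = categorical)
}

#' Write an information system to CSV
#'
#' Values round-trip at full double precision (up to 15 significant
#' digits), so `read_information_system()` on the written file reproduces
#' the system.
#'
#' @param is An `information_system`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_information_system <- function(is, path) {
  stopifnot(inherits(is, "information_system"))
  df <- data.frame(object = is$object_ids,
                   as.data.frame(is$values),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# keep an information_system's roles while replacing its value matrix
replace_values <- function(is, values) {
  information_system(
    values, object_ids = rownames(values),
    decision = if (!is.null(is$decision_attribute) &&
                   is$decision_attribute %in% colnames(values))
      is$decision_attribute,
    time = if (!is.null(is$time_attribute) &&
               is$time_attribute %in% colnames(values)) is$time_attribute,
    event = if (!is.null(is$event_attribute) &&
                is$event_attribute %in% colnames(values)) is$event_attribute,
    categorical = intersect(
      is$attributes$name[is$attributes$kind == "categorical"],
      colnames(values)))
}
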