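#' Individual-level variable (ILV) table
#'
#' One row per individual: `id`, `group` (integer label), `sex`
#' (0 female, 1 male), `age` (years), `rank` (ordinal-averaged score) and
#' `trained` (logical demonstrator flag). Maternal-kin dyads are attached as
#' an unordered pair set.
#'
#' @param df data frame with columns `id`, `group`, `sex`, `age`, `rank`,
#'   `trained`.
#' @param kin optional two-column matrix or data frame of id pairs.
#' @return An object of class `ilv_table` (a data frame with a `kin`
#'   attribute).
#' @export
ilv_table <- function(df, kin = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("id", "group", "sex", "age", "rank", "trained")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("ilv_table: missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$id))
    stop("ilv_table: duplicate id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "), call. = FALSE)
  df$group <- as.integer(df$group)
  df$trained <- as.logical(df$trained)
  if (any(!is.na(df$age) & df$age < 0))
    stop("ilv_table: negative age", call. = FALSE)
  kin <- normalize_kin(kin, df$id)
  structure(reset_rows(df[, required]), kin = kin, class = c("ilv_table", "data.frame"))
}

normalize_kin <- function(kin, ids) {
  if (is.null(kin) || NROW(kin) == 0)
    return(matrix(character(0), ncol = 2, dimnames = list(NULL, c("id_a", "id_b"))))
  kin <- as.matrix(as.data.frame(kin, stringsAsFactors = FALSE))[, 1:2, drop = FALSE]
  mode(kin) <- "character"
  unknown <- setdiff(unique(as.vector(kin)), ids)
  if (length(unknown))
    stop("kin pair refers to unknown id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(kin[, 1] == kin[, 2])) stop("kin pair of an id with itself", call. = FALSE)
  # store unordered: sort within pair, drop duplicates
  swap <- kin[, 1] > kin[, 2]
  kin[swap, ] <- kin[swap, c(2, 1)]
  kin <- unique(kin)
  dimnames(kin) <- list(NULL, c("id_a", "id_b"))
  kin
}

#' Read an ILV table (and optional kin pairs) from delimited files
#'
#' `ilv.csv` columns: `id`, `group`, `sex`, `age_years`, `rank`, `trained`.
#' `kin.csv` columns: `id_a`, `id_b` (unordered pairs).
#'
#' @param path path to the ILV CSV file.
#' @param kin_path optional path to the kin-pair CSV file.
#' @return An [ilv_table()]; the kin relation is symmetric after load.
#' @export
load_ilv_table <- function(path, kin_path = NULL) {
  if (!file.exists(path)) stop("load_ilv_table: file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "group", "sex", "age_years", "rank", "trained")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("load_ilv_table: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- data.frame(id = as.character(raw$id), group = raw$group, sex = raw$sex,
                   age = raw$age_years, rank = raw$rank,
                   trained = as.logical(raw$trained), stringsAsFactors = FALSE)
  kin <- NULL
  if (!is.null(kin_path)) {
    kraw <- utils::read.csv(kin_path, stringsAsFactors = FALSE)
    if (!all(c("id_a", "id_b") %in% names(kraw)))
      stop("kin file must have columns id_a, id_b", call. = FALSE)
    kin <- kraw[, c("id_a", "id_b")]
  }
  ilv_table(df, kin)
}

#' Are two individuals maternal kin?
#'
#' Symmetric lookup in the kin-pair set of an [ilv_table()].
#'
#' @param ilv an [ilv_table()].
#' @param a,b individual ids (vectorized, recycled).
#' @return Logical vector.
#' @export
is_kin <- function(ilv, a, b) {
  kin <- attr(ilv, "kin")
  if (NROW(kin) == 0) return(rep(FALSE, max(length(a), length(b))))
  key <- paste(pmin(a, b), pmax(a, b))
  key %in% paste(kin[, 1], kin[, 2])
}

#' @export
print.ilv_table <- function(x, ...) {
  cat("<ilv_table>", nrow(x), "individuals,",
      length(unique(x$group)), "group(s),",
      sum(x$trained), "trained,", NROW(attr(x, "kin")), "kin pair(s)\n")
  NextMethod()
}
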