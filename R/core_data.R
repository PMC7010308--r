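#' Rearing records
#'
#' A rearing record attributes a number of emerged beetle individuals to the
#' host tree species whose branch section they emerged from, under one of the
#' four spatio-temporal treatments: rain-canopy (`Rc`), rain-ground (`Rg`),
#' dry-canopy (`Dc`) and dry-ground (`Dg`).  Records are long-format rows
#' `(treatment, host, beetle, count[, interval])`; keys may repeat and are
#' summed on aggregation.
#'
#' @param treatment character vector of treatment labels (`Rc`, `Rg`, `Dc`,
#'   `Dg`).
#' @param host,beetle character vectors of species labels (non-empty).
#' @param count non-negative integer vector of emerged individuals.
#' @param interval optional collection-interval label (`"2"`, `"4"`, `"6"`,
#'   `"8"` months); `NA` when emergences were pooled.
#' @return A `data.frame` of class `rearing_records` with one row per record.
#' @examples
#' rearing_records(c("Rc", "Rc"), c("hostA", "hostA"),
#'                 c("bugX", "bugX"), c(2, 3))
#' @export
rearing_records <- function(treatment, host, beetle, count, interval = NA) {
  n <- length(treatment)
  if (length(host) != n || length(beetle) != n || length(count) != n)
    stop("treatment, host, beetle and count must have equal length")
  treatment <- as.character(treatment)
  host <- as.character(host)
  beetle <- as.character(beetle)
  bad <- !treatment %in% TREATMENTS
  if (any(bad))
    stop("unknown treatment label(s): ",
         paste(unique(treatment[bad]), collapse = ", "))
  if (any(!nzchar(host)) || any(!nzchar(beetle)))
    stop("species labels must be non-empty strings")
  if (any(!is.finite(count)) || any(count < 0))
    stop("counts must be finite and non-negative")
  if (any(count != round(count)))
    stop("counts are emerged individuals and must be whole numbers")
  interval <- rep_len(as.character(interval), n)
  ok_int <- is.na(interval) | interval %in% c("2", "4", "6", "8")
  if (!all(ok_int))
    stop("interval labels must be one of 2, 4, 6, 8 (months) or NA")
  out <- data.frame(treatment = treatment, host = host, beetle = beetle,
                    count = as.integer(round(count)), interval = interval,
                    stringsAsFactors = FALSE)
  class(out) <- c("rearing_records", "data.frame")
  out
}

#' Weighted host-by-beetle interaction matrix
#'
#' Constructs the labelled count matrix all network statistics consume.  Rows
#' are host trees, columns are beetles (fixed orientation throughout the
#' package).  All-zero rows and columns are trimmed: a species belongs to a
#' treatment's network only if at least one individual emerged there.  Labels
#' are ordered lexicographically so outputs are byte-stable.
#'
#' @param A numeric matrix of non-negative integer counts with row and column
#'   names (hosts x beetles).
#' @return An `interaction_matrix`: the trimmed integer matrix with attributes
#'   `m` (grand total), and marginal totals available via `rowSums`/`colSums`.
#' @examples
#' interaction_matrix(matrix(c(3, 0, 2, 5), 2, 2,
#'   dimnames = list(c("hA", "hB"), c("bX", "bY"))))
#' @export
interaction_matrix <- function(A) {
  if (!is.matrix(A)) A <- as.matrix(A)
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("interaction matrix needs host row names and beetle column names")
  if (anyDuplicated(rownames(A)) || anyDuplicated(colnames(A)))
    stop("species labels must be unique within each trophic level")
  if (any(!is.finite(A)) || any(A < 0))
    stop("cell counts must be finite and non-negative")
  if (any(A != round(A)))
    stop("cell counts must be integers (emerged individuals)")
  storage.mode(A) <- "integer"
  A <- A[order(rownames(A)), order(colnames(A)), drop = FALSE]
  A <- A[rowSums(A) > 0, colSums(A) > 0, drop = FALSE]
  if (nrow(A) == 0L || ncol(A) == 0L)
    stop("matrix has no non-zero interactions after trimming")
  structure(A, class = c("interaction_matrix", "matrix"), m = sum(A))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix: %d hosts x %d beetles, %d emergences\n",
              nrow(x), ncol(x), sum(x)))
  print(unclass(x)[,], ...)
  invisible(x)
}

#' Grand total of an interaction matrix
#' @param A an `interaction_matrix`.
#' @return Integer sum of all cells.
#' @export
grand_total <- function(A) sum(A)

#' Build one network per treatment from rearing records
#'
#' Aggregates record counts into a weighted host x beetle matrix per
#' treatment.  Repeated `(treatment, host, beetle)` keys (e.g. different
#' collection intervals) are summed; emergences are pooled over intervals
#' unless records are pre-filtered by interval.
#'
#' @param records a `rearing_records` data frame (or compatible data frame
#'   with the same columns).
#' @return A `treatment_network_set`: named list of `interaction_matrix`
#'   objects keyed by treatment label, in the fixed order Rc, Rg, Dc, Dg
#'   (restricted to treatments present).
#' @examples
#' r <- rearing_records(c("Rc", "Rc"), c("hA", "hA"), c("bX", "bX"), c(2, 3))
#' build_networks(r)
#' @export
build_networks <- function(records) {
  records <- as_rearing_records(records)
  present <- TREATMENTS[TREATMENTS %in% unique(records$treatment)]
  if (length(present) == 0L) stop("no records in any treatment")
  nets <- lapply(present, function(tr) {
    sub <- records[records$treatment == tr, , drop = FALSE]
    if (sum(sub$count) == 0L)
      stop("treatment '", tr, "' has no emergences (all counts zero)")
    hosts <- sort(unique(sub$host))
    beetles <- sort(unique(sub$beetle))
    A <- matrix(0L, length(hosts), length(beetles),
                dimnames = list(hosts, beetles))
    agg <- stats::aggregate(count ~ host + beetle, data = sub, FUN = sum)
    A[cbind(match(agg$host, hosts), match(agg$beetle, beetles))] <-
      as.integer(agg$count)
    interaction_matrix(A)
  })
  names(nets) <- present
  structure(nets, class = "treatment_network_set")
}

#' @noRd
as_rearing_records <- function(records) {
  if (inherits(records, "rearing_records")) return(records)
  need <- c("treatment", "host", "beetle", "count")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         "; expected header: treatment,host,beetle,count[,interval]")
  rearing_records(records$treatment, records$host, records$beetle,
                  records$count, records$interval %||% NA)
}

#' @export
print.treatment_network_set <- function(x, ...) {
  cat("treatment_network_set:\n")
  for (tr in names(x))
    cat(sprintf("  %s: %d hosts x %d beetles, %d emergences\n",
                tr, nrow(x[[tr]]), ncol(x[[tr]]), sum(x[[tr]])))
  invisible(x)
}

#' Network size (host species + beetle species)
#'
#' @param set a `treatment_network_set`.
#' @param treatment treatment label.
#' @return Integer: number of host species plus number of beetle species.
#' @export
network_size <- function(set, treatment) {
  A <- set[[treatment]]
  if (is.null(A)) stop("no network for treatment '", treatment, "'")
  nrow(A) + ncol(A)
}

#' Read rearing records from delimited text
#'
#' Expects a header with columns `treatment,host,beetle,count` and optionally
#' `interval`.  Unknown columns are ignored with a warning.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return a `rearing_records` data frame.
#' @export
read_records <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("treatment", "host", "beetle", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         "; expected header: treatment,host,beetle,count[,interval]")
  extra <- setdiff(names(df), c(need, "interval"))
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  rearing_records(df$treatment, df$host, df$beetle, df$count,
                  df$interval %||% NA)
}

#' Write rearing records as CSV
#' @param records a `rearing_records` data frame.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Write an interaction matrix as adjacency CSV
#'
#' First column holds host labels; remaining columns are beetle labels with
#' integer cells.  `read_matrix()` round-trips this dialect exactly.
#'
#' @param A an `interaction_matrix`.
#' @param path output path.
#' @export
write_matrix <- function(A, path) {
  df <- data.frame(host = rownames(A), unclass(A)[,, drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an adjacency CSV written by [write_matrix()]
#' @param path file path.
#' @return an `interaction_matrix`.
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("adjacency CSV needs a host column plus beetles")
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df[[1]]
  interaction_matrix(A)
}

#' Species trait table
#'
#' Validates a long trait table: hosts carry wood density (g/cm^3) and
#' percent daily decomposition; beetles carry the body-size index (mm^2).
#' Role-inappropriate trait cells must be empty.
#'
#' @param df data frame with columns `species, role, wood_density, pdd, bsi`
#'   (missing trait columns are added as `NA`).
#' @return A validated `trait_table` data frame.
#' @export
trait_table <- function(df) {
  need <- c("species", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trait table missing column(s): ", paste(miss, collapse = ", "),
         "; expected header: species,role,wood_density,pdd,bsi")
  for (col in c("wood_density", "pdd", "bsi"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  df <- df[, c("species", "role", "wood_density", "pdd", "bsi")]
  if (!all(df$role %in% c("host", "beetle")))
    stop("role must be 'host' or 'beetle'")
  h <- df$role == "host"
  if (any(!is.na(df$bsi[h])))
    stop("host rows must not carry bsi")
  if (any(!is.na(df$wood_density[!h])) || any(!is.na(df$pdd[!h])))
    stop("beetle rows must not carry wood_density or pdd")
  num <- c(df$wood_density[h], df$bsi[!h])
  if (any(!is.na(num) & (num < 0 | !is.finite(num))))
    stop("trait values must be finite and non-negative")
  if (anyDuplicated(paste(df$species, df$role)))
    stop("duplicate species within a role")
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a species trait CSV
#' @param path file path (`species,role,wood_density,pdd,bsi`; empty cells
#'   where a trait does not apply to the role).
#' @return a `trait_table`.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  trait_table(df)
}

#' Write a species trait CSV
#' @param traits a `trait_table`.
#' @param path output path.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
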