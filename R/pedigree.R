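#' Build a validated pedigree
#'
#' Assembles a pedigree from individual/sire/dam records, validates it, and
#' orders it so that parents always precede their offspring. Unknown parents
#' are encoded as `NA`, the empty string, or `"0"` and are treated as
#' unrelated, non-inbred founders.
#'
#' @param records A data frame with columns `id`, `sire`, `dam` (coerced to
#'   character). One row per individual; founders carry unknown parents.
#' @param allow_implicit_founders If `TRUE`, a parent id that never appears in
#'   the `id` column is auto-inserted as a founder row; if `FALSE` (default)
#'   such a reference is an error.
#' @return A tibble of class `pedigree` with columns `id`, `sire`, `dam`
#'   (character; `NA` for unknown parents), topologically ordered.
#' @examples
#' ped <- build_pedigree(tibble::tibble(
#'   id = c("s1", "d1", "o1"), sire = c(NA, NA, "s1"), dam = c(NA, NA, "d1")
#' ))
#' @export
build_pedigree <- function(records, allow_implicit_founders = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(records))) {
    stop("`records` must have columns id, sire, dam", call. = FALSE)
  }
  ped <- tibble::tibble(
    id   = as.character(records$id),
    sire = normalize_parent(records$sire),
    dam  = normalize_parent(records$dam)
  )
  if (nrow(ped) == 0L) {
    return(structure(ped, class = c("pedigree", class(ped))))
  }
  if (anyNA(ped$id) || any(ped$id == "")) {
    stop("individual ids must be non-missing and non-empty", call. = FALSE)
  }
  dup <- ped$id[duplicated(ped$id)]
  if (length(dup)) {
    stop("duplicate individual id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(parents)) {
    if (!allow_implicit_founders) {
      stop("parent id(s) never listed as individuals: ",
           paste(parents, collapse = ", "),
           "; set allow_implicit_founders = TRUE to auto-insert them",
           call. = FALSE)
    }
    ped <- dplyr::bind_rows(
      tibble::tibble(id = parents, sire = NA_character_, dam = NA_character_),
      ped
    )
  }
  ped <- topo_sort_pedigree(ped)
  structure(ped, class = c("pedigree", class(tibble::tibble())))
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
  x
}

# Kahn's algorithm on the parent -> offspring DAG; detects cycles
# (including an individual listed as its own parent).
topo_sort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  if (any(si == seq_len(n), na.rm = TRUE) || any(di == seq_len(n), na.rm = TRUE)) {
    stop("pedigree cycle: individual listed as its own parent", call. = FALSE)
  }
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    # stable order keeps output deterministic for a given input order
    queue <- sort(queue)
    i <- queue[1]
    queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) {
    stop("pedigree cycle detected among: ",
         paste(ped$id[setdiff(seq_len(n), out)], collapse = ", "),
         call. = FALSE)
  }
  ped[out, ]
}

#' Additive genetic relationship matrix
#'
#' Computes the numerator relationship matrix A from a pedigree by the
#' recursive tabular method: processing individuals in generation order,
#' `A[i, j] = (A[j, sire(i)] + A[j, dam(i)]) / 2` for earlier `j`, and
#' `A[i, i] = 1 + A[sire(i), dam(i)] / 2`, an unknown parent contributing 0.
#'
#' @param ped A `pedigree` from [build_pedigree()].
#' @return A dense symmetric numeric matrix with dimnames equal to the
#'   pedigree ids (in pedigree order).
#' @export
additive_relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  if (n == 0L) return(A)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[j, s]
      if (!is.na(d)) row <- row + 0.5 * A[j, d]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Read a pedigree from CSV
#'
#' Expects header `id,sire,dam`; unknown parents are empty fields or `0`.
#'
#' @inheritParams build_pedigree
#' @param path Path to a CSV file.
#' @return A `pedigree` tibble.
#' @export
read_pedigree <- function(path, allow_implicit_founders = FALSE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("id", "sire", "dam") %in% names(raw))) {
    stop("pedigree file must have header id,sire,dam: ", path, call. = FALSE)
  }
  build_pedigree(raw, allow_implicit_founders = allow_implicit_founders)
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(is.na(x$sire) & is.na(x$dam))
  cat("<pedigree> ", nrow(x), " individuals (", founders, " founders)\n", sep = "")
  NextMethod()
}
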