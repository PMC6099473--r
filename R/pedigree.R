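#' Construct a validated pedigree
#'
#' A pedigree is a directed acyclic parent map. Each individual has at most one
#' sire and one dam; parents that are named but have no record of their own are
#' added as implicit founders (sex inferred from the slot they occupy).
#' Founders are, by construction, assumed unrelated and non-inbred.
#'
#' @param id character vector of unique identifiers.
#' @param sire,dam character vectors of parent identifiers; `NA` (or `""`) for
#'   a missing parent.
#' @param cohort optional integer birth year per individual.
#' @param sex optional vector with values `"male"`, `"female"` or `"unknown"`
#'   (`NA` is treated as unknown).
#' @return An object of class `pedigree`: a list with element `records`
#'   (a data frame with columns `id`, `sire`, `dam`, `cohort`, `sex`) plus
#'   internal index structures used by the kinship routines.
#' @examples
#' ped <- pedigree(id   = c("A", "B", "C"),
#'                 sire = c(NA, NA, "A"),
#'                 dam  = c(NA, NA, "B"))
#' inbreeding(ped, "C")
#' @export
pedigree <- function(id, sire, dam, cohort = NULL, sex = NULL) {
  id   <- as.character(id)
  sire <- blank_to_na(as.character(sire))
  dam  <- blank_to_na(as.character(dam))
  n0 <- length(id)
  stopifnot(length(sire) == n0, length(dam) == n0)
  if (is.null(cohort)) cohort <- rep(NA_integer_, n0)
  cohort <- as.integer(cohort)
  if (is.null(sex)) sex <- rep(NA_character_, n0)
  sex <- normalize_sex(as.character(sex))

  dup <- id[duplicated(id)]
  if (length(dup)) {
    stop("duplicate id in pedigree: ", paste(unique(dup), collapse = ", "))
  }
  self <- id[!is.na(sire) & sire == id | !is.na(dam) & dam == id]
  if (length(self)) {
    stop("record lists itself as a parent: ", paste(self, collapse = ", "))
  }

  # implicit founders for named-but-absent parents
  extra_sires <- setdiff(stats::na.omit(sire), id)
  extra_dams  <- setdiff(stats::na.omit(dam), id)
  both <- intersect(extra_sires, extra_dams)
  if (length(both)) {
    stop("identifier used as both sire and dam without a record: ",
         paste(both, collapse = ", "))
  }
  if (length(extra_sires) || length(extra_dams)) {
    id     <- c(id, extra_sires, extra_dams)
    sire   <- c(sire, rep(NA_character_, length(extra_sires) + length(extra_dams)))
    dam    <- c(dam,  rep(NA_character_, length(extra_sires) + length(extra_dams)))
    cohort <- c(cohort, rep(NA_integer_,  length(extra_sires) + length(extra_dams)))
    sex    <- c(sex, rep("male", length(extra_sires)), rep("female", length(extra_dams)))
  }
  n <- length(id)
  index <- stats::setNames(seq_len(n), id)

  # sex consistency of recorded parents
  sire_sex <- sex[index[stats::na.omit(unique(sire))]]
  bad <- stats::na.omit(unique(sire))[!is.na(sire_sex) & sire_sex == "female"]
  if (length(bad)) stop("sire recorded as female: ", paste(bad, collapse = ", "))
  dam_sex <- sex[index[stats::na.omit(unique(dam))]]
  bad <- stats::na.omit(unique(dam))[!is.na(dam_sex) & dam_sex == "male"]
  if (length(bad)) stop("dam recorded as male: ", paste(bad, collapse = ", "))

  sire_idx <- ifelse(is.na(sire), NA_integer_, index[sire])
  dam_idx  <- ifelse(is.na(dam),  NA_integer_, index[dam])

  rank <- ped_rank(sire_idx, dam_idx, id)

  structure(
    list(
      records = data.frame(id = id, sire = sire, dam = dam,
                           cohort = cohort, sex = sex,
                           stringsAsFactors = FALSE),
      index = index,
      sire_idx = as.integer(sire_idx),
      dam_idx = as.integer(dam_idx),
      rank = rank
    ),
    class = "pedigree"
  )
}

blank_to_na <- function(x) {
  x[!is.na(x) & (x == "" | x == "NA")] <- NA_character_
  x
}

normalize_sex <- function(x) {
  x <- tolower(x)
  x[is.na(x) | x %in% c("", "u", "unknown", "0")] <- "unknown"
  x[x %in% c("m", "1")] <- "male"
  x[x %in% c("f", "2")] <- "female"
  bad <- setdiff(unique(x), c("male", "female", "unknown"))
  if (length(bad)) stop("unrecognized sex code: ", paste(bad, collapse = ", "))
  x
}

# Topological depth from founders (founders 0, otherwise 1 + max parent rank).
# Kahn's algorithm; leftover nodes indicate a cycle and are named in the error.
ped_rank <- function(sire_idx, dam_idx, id) {
  n <- length(id)
  indeg <- (!is.na(sire_idx)) + (!is.na(dam_idx))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_idx[i], dam_idx[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  rank <- rep(NA_integer_, n)
  queue <- which(indeg == 0L)
  rank[queue] <- 0L
  head <- 1L
  queue <- as.integer(queue)
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (ch in children[[v]]) {
      pr <- c(rank[sire_idx[ch]], rank[dam_idx[ch]])
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) {
        rank[ch] <- max(pr, na.rm = TRUE) + 1L
        queue <- c(queue, ch)
      }
    }
  }
  if (anyNA(rank)) {
    stop("pedigree contains a cycle involving: ",
         paste(id[is.na(rank)], collapse = ", "))
  }
  rank
}

#' @export
print.pedigree <- function(x, ...) {
  r <- x$records
  cat("<pedigree> ", nrow(r), " individuals (",
      sum(is.na(r$sire) & is.na(r$dam)), " founders), max depth ",
      max(x$rank), " generations\n", sep = "")
  invisible(x)
}

#' Number of individuals in a pedigree
#' @param ped a [pedigree] object.
#' @return Integer count of records.
#' @export
n_individuals <- function(ped) nrow(ped$records)

#' Identifiers of all pedigree members
#' @param ped a [pedigree] object.
#' @return Character vector of ids.
#' @export
ped_ids <- function(ped) ped$records$id

# resolve ids to row indices, erroring on unknown identifiers
ped_index <- function(ped, ids) {
  i <- ped$index[as.character(ids)]
  if (anyNA(i)) {
    stop("unknown identifier: ",
         paste(as.character(ids)[is.na(i)], collapse = ", "))
  }
  unname(i)
}

# 0-based parent arrays for the compiled routines
ped_arrays <- function(ped) {
  list(
    sire = as.integer(ifelse(is.na(ped$sire_idx), -1L, ped$sire_idx - 1L)),
    dam  = as.integer(ifelse(is.na(ped$dam_idx),  -1L, ped$dam_idx  - 1L)),
    rank = as.integer(ped$rank)
  )
}

#' Read a pedigree from a delimited file
#'
#' Two dialects are supported. `"csv"` expects a header
#' `id,sire,dam,cohort,sex` with empty fields for missing values and sex coded
#' `male`/`female`/empty. `"linkage"` expects whitespace-separated columns
#' `family id sire dam sex` with `0` for a missing parent and sex coded
#' 1 = male, 2 = female, 0 = unknown.
#'
#' @param path path to the file.
#' @param dialect `"csv"` (default) or `"linkage"`.
#' @return A validated [pedigree].
#' @export
read_pedigree <- function(path, dialect = c("csv", "linkage")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- c("id", "sire", "dam")
    if (!all(need %in% names(df))) {
      stop("pedigree csv must have columns id, sire, dam (cohort, sex optional)")
    }
    pedigree(df$id, df$sire, df$dam,
             cohort = if ("cohort" %in% names(df))
               suppressWarnings(as.integer(df$cohort)) else NULL,
             sex = if ("sex" %in% names(df)) df$sex else NULL)
  } else {
    df <- utils::read.table(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (ncol(df) < 5) stop("linkage file needs columns: family id sire dam sex")
    names(df)[1:5] <- c("family", "id", "sire", "dam", "sex")
    sire <- ifelse(df$sire == "0", NA_character_, df$sire)
    dam  <- ifelse(df$dam  == "0", NA_character_, df$dam)
    pedigree(df$id, sire, dam, sex = df$sex)
  }
}

#' Write a pedigree to a delimited file
#'
#' @inheritParams read_pedigree
#' @param ped a [pedigree] object.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, dialect = c("csv", "linkage")) {
  dialect <- match.arg(dialect)
  r <- ped$records
  if (dialect == "csv") {
    out <- data.frame(
      id = r$id,
      sire = ifelse(is.na(r$sire), "", r$sire),
      dam = ifelse(is.na(r$dam), "", r$dam),
      cohort = ifelse(is.na(r$cohort), "", as.character(r$cohort)),
      sex = ifelse(r$sex == "unknown", "", r$sex),
      stringsAsFactors = FALSE
    )
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    out <- data.frame(
      family = "1",
      id = r$id,
      sire = ifelse(is.na(r$sire), "0", r$sire),
      dam = ifelse(is.na(r$dam), "0", r$dam),
      sex = c(male = "1", female = "2", unknown = "0")[r$sex],
      stringsAsFactors = FALSE
    )
    utils::write.table(out, path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
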