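#' Pedigree kinship coefficient
#'
#' The kinship coefficient k(i, j) is the probability that one allele sampled
#' from i and one from j are identical by descent. It is computed by the
#' Malecot recursion: the individual of greater generation depth is decomposed
#' onto its parents, founders are mutually unrelated and non-inbred, and
#' k(i, i) = (1 + f_i) / 2. It equals the inbreeding coefficient of an
#' offspring the pair would produce.
#'
#' @param ped a [pedigree].
#' @param i,j identifiers present in the pedigree. Vectors of equal length are
#'   accepted and evaluated pairwise.
#' @return For scalar input, a list of class `kinship_result` with elements
#'   `pair` and `kinship`; for vector input, a numeric vector of kinship
#'   values.
#' @examples
#' ped <- pedigree(c("A", "B", "S"), c(NA, NA, "A"), c(NA, NA, "B"))
#' kinship(ped, "B", "S")$kinship  # mother and son: 0.25
#' @export
kinship <- function(ped, i, j) {
  ii <- ped_index(ped, i)
  jj <- ped_index(ped, j)
  stopifnot(length(ii) == length(jj))
  arr <- ped_arrays(ped)
  k <- .kinship_pairs_cpp(arr$sire, arr$dam, arr$rank,
                          as.integer(ii - 1L), as.integer(jj - 1L))
  if (length(ii) == 1L) {
    structure(list(pair = c(as.character(i), as.character(j)), kinship = k),
              class = "kinship_result")
  } else {
    k
  }
}

#' @export
print.kinship_result <- function(x, ...) {
  cat("kinship(", x$pair[1], ", ", x$pair[2], ") = ", format(x$kinship),
      "\n", sep = "")
  invisible(x)
}

#' Pedigree inbreeding coefficient
#'
#' f equals the kinship of the individual's parents; by convention f = 0 when
#' either parent is unknown (the unknown side contributes no identity by
#' descent). The number of known grandparents is reported alongside so that
#' completeness restrictions can be applied downstream.
#'
#' @param ped a [pedigree].
#' @param i one identifier, or a vector of identifiers.
#' @return For scalar input, a list of class `inbreeding_result` with elements
#'   `id`, `f` and `n_known_grandparents`; for vector input, a numeric vector
#'   of f values.
#' @export
inbreeding <- function(ped, i) {
  ii <- ped_index(ped, i)
  arr <- ped_arrays(ped)
  s <- ped$sire_idx[ii]
  d <- ped$dam_idx[ii]
  f <- numeric(length(ii))
  both <- !is.na(s) & !is.na(d)
  if (any(both)) {
    f[both] <- .kinship_pairs_cpp(arr$sire, arr$dam, arr$rank,
                                  as.integer(s[both] - 1L),
                                  as.integer(d[both] - 1L))
  }
  if (length(ii) == 1L) {
    structure(list(id = as.character(i), f = f,
                   n_known_grandparents = known_grandparent_count(ped, i)),
              class = "inbreeding_result")
  } else {
    f
  }
}

#' @export
print.inbreeding_result <- function(x, ...) {
  cat("f(", x$id, ") = ", format(x$f), " [", x$n_known_grandparents,
      " known grandparents]\n", sep = "")
  invisible(x)
}

# f for every individual in the pedigree, in record order
inbreeding_all <- function(ped) {
  arr <- ped_arrays(ped)
  .inbreeding_all_cpp(arr$sire, arr$dam, arr$rank)
}

# restrict a pedigree to ids and all their ancestors, in topological order;
# returns the sub-arrays and the positions of `ids` within them
prune_to_ancestors <- function(ped, ids) {
  ii <- ped_index(ped, ids)
  keep <- logical(n_individuals(ped))
  stack <- ii
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (!keep[v]) {
      keep[v] <- TRUE
      for (p in c(ped$sire_idx[v], ped$dam_idx[v])) {
        if (!is.na(p) && !keep[p]) stack <- c(stack, p)
      }
    }
  }
  rows <- which(keep)
  rows <- rows[order(ped$rank[rows], rows)]
  pos <- match(seq_len(n_individuals(ped)), rows)  # old index -> new row
  list(
    sire = as.integer(ifelse(is.na(ped$sire_idx[rows]), -1L,
                             pos[ped$sire_idx[rows]] - 1L)),
    dam  = as.integer(ifelse(is.na(ped$dam_idx[rows]), -1L,
                             pos[ped$dam_idx[rows]] - 1L)),
    ids  = ped$records$id[rows],
    at   = pos[ii]
  )
}

#' Additive (numerator) relationship matrix
#'
#' Builds the additive relationship matrix A with A\[i, j\] = 2 k(i, j) by the
#' tabular method, processing individuals in topological order over the
#' requested ids and all their ancestors. Diagonal entries equal 1 + f.
#'
#' @param ped a [pedigree].
#' @param ids ordered identifiers for the rows/columns of the result.
#' @return A dense symmetric numeric matrix with `dimnames` equal to `ids`.
#' @export
relationship_matrix <- function(ped, ids) {
  ids <- as.character(ids)
  sub <- prune_to_ancestors(ped, ids)
  A <- .amatrix_cpp(sub$sire, sub$dam)
  out <- A[sub$at, sub$at, drop = FALSE]
  dimnames(out) <- list(ids, ids)
  out
}

#' Monte Carlo gene-drop estimate of kinship
#'
#' Transmits founder-unique alleles down the pedigree by Mendelian sampling
#' and estimates k(i, j) as the fraction of replicates in which one allele
#' drawn from i and one from j are identical by descent. This is a slow but
#' assumption-free cross-check of the exact recursion. Reproducible under
#' `set.seed()` via the supplied seed.
#'
#' @param ped a [pedigree].
#' @param i,j identifiers.
#' @param n_reps number of replicates (at least 1000).
#' @param seed integer seed.
#' @return List with `estimate`, `se` (binomial standard error) and `n_reps`.
#' @export
gene_drop_kinship <- function(ped, i, j, n_reps = 100000L, seed = 1L) {
  stopifnot(n_reps >= 1000L)
  sub <- prune_to_ancestors(ped, c(i, j))
  at <- sub$at
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  hits <- .gene_drop_cpp(sub$sire, sub$dam, at[1L] - 1L, at[2L] - 1L,
                         as.integer(n_reps))
  p <- hits / n_reps
  list(estimate = p, se = sqrt(p * (1 - p) / n_reps), n_reps = n_reps)
}

#' Count known grandparents
#'
#' Counts, over the four grandparent slots (paternal sire/dam, maternal
#' sire/dam), those where the intermediate parent is recorded and that
#' parent's relevant parent is recorded too.
#'
#' @param ped a [pedigree].
#' @param i identifier(s).
#' @return Integer vector of counts in 0..4.
#' @export
known_grandparent_count <- function(ped, i) {
  ii <- ped_index(ped, i)
  s <- ped$sire_idx[ii]
  d <- ped$dam_idx[ii]
  cnt <- integer(length(ii))
  hs <- !is.na(s)
  cnt[hs] <- cnt[hs] + (!is.na(ped$sire_idx[s[hs]])) + (!is.na(ped$dam_idx[s[hs]]))
  hd <- !is.na(d)
  cnt[hd] <- cnt[hd] + (!is.na(ped$sire_idx[d[hd]])) + (!is.na(ped$dam_idx[d[hd]]))
  cnt
}

#' Restrict a pedigree by completeness
#'
#' Returns the ids whose both genetic parents are recorded and whose number of
#' known grandparents is at least `min_grandparents`. The returned set shrinks
#' (weakly) as the threshold rises.
#'
#' @param ped a [pedigree].
#' @param min_grandparents integer in 0..4.
#' @return Character vector of retained ids.
#' @export
restrict_pedigree <- function(ped, min_grandparents = 1L) {
  stopifnot(min_grandparents >= 0, min_grandparents <= 4)
  both <- !is.na(ped$sire_idx) & !is.na(ped$dam_idx)
  ids <- ped$records$id[both]
  if (min_grandparents > 0 && length(ids)) {
    ids <- ids[known_grandparent_count(ped, ids) >= min_grandparents]
  }
  ids
}

#' Classify the relationship between a male and a female
#'
#' Labels the closest-path relationship by inspecting shared ancestors up to
#' two generations, in the orientation of a social pair (male `i`, female
#' `j`). Pairs with zero kinship are `unrelated`; related pairs that do not
#' match a named route are `other_related`.
#'
#' @param ped a [pedigree].
#' @param i male identifier.
#' @param j female identifier.
#' @return One of `"mother_son"`, `"father_daughter"`, `"full_sib"`,
#'   `"paternal_half_sib"`, `"maternal_half_sib"`, `"grandmother_grandson"`,
#'   `"grandfather_granddaughter"`, `"other_related"`, `"unrelated"`.
#' @export
classify_relationship <- function(ped, i, j) {
  ii <- ped_index(ped, i)
  jj <- ped_index(ped, j)
  stopifnot(length(ii) == length(jj))
  out <- character(length(ii))
  for (r in seq_along(ii)) {
    out[r] <- classify_one(ped, ii[r], jj[r])
  }
  out
}

classify_one <- function(ped, ii, jj) {
  s_i <- ped$sire_idx[ii]; d_i <- ped$dam_idx[ii]
  s_j <- ped$sire_idx[jj]; d_j <- ped$dam_idx[jj]
  same <- function(a, b) !is.na(a) && !is.na(b) && a == b
  # parent-offspring routes (male i, female j)
  if (same(d_i, jj)) return("mother_son")
  if (same(s_j, ii)) return("father_daughter")
  if (same(s_i, s_j) && same(d_i, d_j)) return("full_sib")
  if (same(s_i, s_j)) return("paternal_half_sib")
  if (same(d_i, d_j)) return("maternal_half_sib")
  # grandparental routes: j a grandmother of male i, or i a grandfather of j
  gm_i <- c(ped$dam_idx[s_i], ped$dam_idx[d_i])  # paternal / maternal grandmother
  if (any(!is.na(gm_i) & gm_i == jj)) return("grandmother_grandson")
  gf_j <- c(ped$sire_idx[s_j], ped$sire_idx[d_j])
  if (any(!is.na(gf_j) & gf_j == ii)) return("grandfather_granddaughter")
  arr <- ped_arrays(ped)
  k <- .kinship_pairs_cpp(arr$sire, arr$dam, arr$rank,
                          as.integer(ii - 1L), as.integer(jj - 1L))
  if (k > 1e-12) "other_related" else "unrelated"
}
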