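#' Construct a validated pedigree
#'
#' A pedigree is a directed acyclic family graph. Each individual carries a
#' family identifier, optional parent identifiers, sex, and a three-state
#' affection phenotype (`"unaffected"`, `"CD"`, `"UC"`, or `"unknown"`) so
#' that case sets can be restricted to a disease subtype. Loops arising from
#' consanguineous matings (e.g. first-cousin marriages) are permitted; cycles
#' in the parent graph (an individual being its own ancestor) are not.
#'
#' Founders are individuals with both parents absent. Individuals with
#' exactly one recorded parent are rejected: the file dialect used here
#' (PLINK FAM) records unknown parents as `0`, and a half-known parent pair
#' cannot be traversed by the kinship recursion.
#'
#' @param df data.frame with columns `family`, `id`, `father`, `mother`,
#'   `sex`, `affection`. Parent codes `0`, `""` and `NA` mean "absent".
#'   `sex` may be `1`/`2`/`0` (PLINK) or `"male"`/`"female"`/`"unknown"`.
#'   `affection` may be `"unaffected"`, `"CD"`, `"UC"`, `"unknown"`, or the
#'   extended PLINK phenotype codes `1` (unaffected), `2` (CD), `3` (UC),
#'   `0`/`-9` (unknown).
#' @param proband optional id of the index case.
#' @return an object of class `pedigree`: a data.frame with normalised
#'   columns `family`, `id`, `father`, `mother` (`NA` = absent), `sex`,
#'   `affection`, plus attributes `proband` and `founder` (logical).
#' @examples
#' trio <- pedigree(data.frame(
#'   family = "F", id = c("dad", "mum", "kid"),
#'   father = c(0, 0, "dad"), mother = c(0, 0, "mum"),
#'   sex = c(1, 2, 1), affection = c(1, 1, 2)))
#' sum(is_founder(trio))  # 2
#' @export
pedigree <- function(df, proband = NULL) {
  req <- c("family", "id", "father", "mother", "sex", "affection")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("pedigree table lacks columns: ", paste(miss, collapse = ", "))
  id <- as.character(df$id)
  if (anyDuplicated(id))
    stop("duplicate individual ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  absent <- function(x) is.na(x) | x == "0" | x == ""
  fa <- as.character(df$father); fa[absent(fa)] <- NA_character_
  mo <- as.character(df$mother); mo[absent(mo)] <- NA_character_
  if (any(xor(is.na(fa), is.na(mo))))
    stop("individuals with exactly one known parent are not supported: ",
         paste(id[xor(is.na(fa), is.na(mo))], collapse = ", "))
  bad <- !is.na(fa) & !(fa %in% id)
  if (any(bad)) stop("unresolved father id: ", paste(unique(fa[bad]), collapse = ", "))
  bad <- !is.na(mo) & !(mo %in% id)
  if (any(bad)) stop("unresolved mother id: ", paste(unique(mo[bad]), collapse = ", "))

  sex <- as.character(df$sex)
  sex <- c("1" = "male", "2" = "female", "0" = "unknown",
           male = "male", female = "female", unknown = "unknown")[sex]
  if (anyNA(sex)) stop("unrecognised sex code")
  aff <- as.character(df$affection)
  aff <- c("1" = "unaffected", "2" = "CD", "3" = "UC", "0" = "unknown",
           "-9" = "unknown", unaffected = "unaffected", CD = "CD", UC = "UC",
           unknown = "unknown")[aff]
  if (anyNA(aff)) stop("unrecognised affection code")

  # parent sex consistency
  pos <- setNames(seq_along(id), id)
  if (any(!is.na(fa) & sex[pos[fa]] == "female"))
    stop("father with sex=female")
  if (any(!is.na(mo) & sex[pos[mo]] == "male"))
    stop("mother with sex=male")

  depth <- ped_depths(id, fa, mo)  # errors on cycles
  if (!any(is.na(fa) & is.na(mo))) stop("pedigree has no founder")
  if (!is.null(proband) && !(proband %in% id))
    stop("proband id not in pedigree: ", proband)

  out <- data.frame(family = as.character(df$family), id = id,
                    father = fa, mother = mo, sex = sex, affection = aff,
                    stringsAsFactors = FALSE)
  rownames(out) <- id
  attr(out, "proband") <- proband
  attr(out, "depth") <- depth
  class(out) <- c("pedigree", "data.frame")
  out
}

# generation depth of every individual (founder = 0); stops on cycles
ped_depths <- function(id, fa, mo) {
  pos <- setNames(seq_along(id), id)
  depth <- rep(NA_integer_, length(id))
  state <- integer(length(id))  # 0 untouched, 1 in progress, 2 done
  visit <- function(i) {
    if (state[i] == 1L) stop("cycle detected in pedigree at individual ", id[i])
    if (state[i] == 2L) return(depth[i])
    state[i] <<- 1L
    d <- if (is.na(fa[i])) 0L else
      1L + max(visit(pos[[fa[i]]]), visit(pos[[mo[i]]]))
    depth[i] <<- d
    state[i] <<- 2L
    d
  }
  for (i in seq_along(id)) visit(i)
  depth
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals (%d founders), family %s\n",
              nrow(x), sum(is_founder(x)),
              paste(unique(x$family), collapse = ",")))
  if (!is.null(attr(x, "proband")))
    cat("proband:", attr(x, "proband"), "\n")
  NextMethod()
}

#' Founder indicator
#'
#' @param ped a [pedigree].
#' @return logical vector, `TRUE` where both parents are absent.
#' @export
is_founder <- function(ped) is.na(ped$father) & is.na(ped$mother)

#' Case/control id helpers
#'
#' `affected_ids` returns ids whose affection matches `subtype`
#' (`"any"` means CD or UC); `control_ids` returns unaffected ids.
#'
#' @param ped a [pedigree].
#' @param subtype `"any"`, `"CD"` or `"UC"`.
#' @return character vector of ids.
#' @export
affected_ids <- function(ped, subtype = c("any", "CD", "UC")) {
  subtype <- match.arg(subtype)
  if (subtype == "any") ped$id[ped$affection %in% c("CD", "UC")]
  else ped$id[ped$affection == subtype]
}

#' @rdname affected_ids
#' @export
control_ids <- function(ped) ped$id[ped$affection == "unaffected"]

#' Read / write PLINK-style FAM pedigree files
#'
#' Six whitespace-separated columns: family, id, father, mother, sex
#' (1=male, 2=female, 0=unknown) and phenotype. The phenotype column uses an
#' extension of the PLINK case code to keep the IBD subtype: 1 unaffected,
#' 2 CD, 3 UC, 0/-9 unknown.
#'
#' @param path file path.
#' @param proband optional proband id passed to [pedigree()].
#' @return `read_fam` returns a [pedigree]; `write_fam` returns `path`
#'   invisibly.
#' @export
read_fam <- function(path, proband = NULL) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 6) stop("FAM file must have 6 columns")
  names(df)[1:6] <- c("family", "id", "father", "mother", "sex", "affection")
  pedigree(df[1:6], proband = proband)
}

#' @param ped a [pedigree].
#' @rdname read_fam
#' @export
write_fam <- function(ped, path) {
  sex <- c(male = 1L, female = 2L, unknown = 0L)[ped$sex]
  aff <- c(unaffected = 1L, CD = 2L, UC = 3L, unknown = 0L)[ped$affection]
  out <- data.frame(ped$family, ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    sex, aff)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pedigree kinship coefficient
#'
#' The kinship coefficient phi(i, j) is the probability that one allele
#' drawn at random from individual `i` and one from `j` are identical by
#' descent. It is computed by the standard recursion on parents, with
#' founders assumed mutually unrelated and non-inbred:
#' phi(i, i) = (1 + F(i)) / 2 and, for j not an ancestor of i,
#' phi(i, j) = (phi(i, father(j)) + phi(i, mother(j))) / 2.
#'
#' @param ped a [pedigree].
#' @param i,j individual ids.
#' @return the kinship coefficient, a fraction in `[0, (1 + F)/2]`.
#' @examples
#' trio <- pedigree(data.frame(
#'   family = "F", id = c("f", "m", "c"), father = c(0, 0, "f"),
#'   mother = c(0, 0, "m"), sex = c(1, 2, 1), affection = 1))
#' kinship_coefficient(trio, "f", "c")  # 0.25
#' @export
kinship_coefficient <- function(ped, i, j) {
  km <- kinship_env(ped)
  km$phi(i, j)
}

#' Inbreeding coefficient
#'
#' F(i) is the kinship coefficient of the parents of `i`; 0 for founders.
#'
#' @inheritParams kinship_coefficient
#' @return fraction in `[0, 1]`.
#' @export
inbreeding_coefficient <- function(ped, i) {
  if (!(i %in% ped$id)) stop("id not found: ", i)
  if (is.na(ped[i, "father"])) return(0)
  kinship_coefficient(ped, ped[i, "father"], ped[i, "mother"])
}

#' Kinship matrix for all pairs
#'
#' @param ped a [pedigree].
#' @param ids optional subset of ids (default all).
#' @return symmetric numeric matrix of kinship coefficients with
#'   self-kinship (1 + F)/2 on the diagonal.
#' @export
kinship_matrix <- function(ped, ids = ped$id) {
  km <- kinship_env(ped)
  n <- length(ids)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) for (b in a:n)
    out[a, b] <- out[b, a] <- km$phi(ids[a], ids[b])
  out
}

# memoised recursion closure; recursion always descends on the individual
# with the larger generation depth, which can never be an ancestor of the
# other, so termination is guaranteed even with consanguineous loops
kinship_env <- function(ped) {
  depth <- setNames(attr(ped, "depth"), ped$id)
  fa <- setNames(ped$father, ped$id)
  mo <- setNames(ped$mother, ped$id)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  phi <- function(i, j) {
    if (!(i %in% names(fa))) stop("id not found: ", i)
    if (!(j %in% names(fa))) stop("id not found: ", j)
    key <- paste(sort(c(i, j)), collapse = "\r")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <-
      if (i == j) {
        if (is.na(fa[[i]])) 0.5 else 0.5 * (1 + phi(fa[[i]], mo[[i]]))
      } else {
        # recurse on the deeper individual
        if (depth[[j]] < depth[[i]]) { tmp <- i; i <- j; j <- tmp }
        if (is.na(fa[[j]])) 0 else 0.5 * (phi(i, fa[[j]]) + phi(i, mo[[j]]))
      }
    cache[[key]] <- val
    val
  }
  list(phi = phi)
}

#' Expected pairwise kinship for all genotyped pairs
#'
#' Convenience wrapper returning a data.frame of expected kinship values for
#' every unordered pair of the given ids, used by [verify_relatedness()].
#'
#' @param ped a [pedigree].
#' @param ids ids to pair up.
#' @return data.frame with columns `id1`, `id2`, `expected_kinship`.
#' @keywords internal
expected_kinship_pairs <- function(ped, ids) {
  km <- kinship_env(ped)
  pairs <- utils::combn(ids, 2)
  data.frame(id1 = pairs[1, ], id2 = pairs[2, ],
             expected_kinship = apply(pairs, 2, function(p) km$phi(p[1], p[2])),
             stringsAsFactors = FALSE)
}
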