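#' Pedigree objects
#'
#' A `Pedigree` is a validated family structure: an ordered set of members
#' with parent links forming a directed acyclic graph.  Founders are members
#' with both parents missing; every non-founder has both parents present in
#' the pedigree (half-specified parentage is rejected).  Fathers must be male
#' (or unknown-sex founders), mothers female likewise; unknown sex is allowed
#' for founders only.
#'
#' @param family_id family identifier (scalar character).
#' @param id,father,mother character vectors of member and parent IDs; the
#'   missing-parent marker is `NA` (file readers map the code `"0"`).
#' @param sex character vector in `c("male", "female", "unknown")`.
#' @param strict_parents if `TRUE`, a parent ID that is not itself listed as
#'   a member is a structural error; by default such parents are auto-added
#'   as founders of unknown sex with a warning, the common convention in
#'   workshop-style ped files that omit founding spouses.
#' @param rows optional original file row numbers, used in error messages.
#'
#' @return An object of class `Pedigree`: a list with elements `family_id`,
#'   `members` (data.frame with columns `id`, `father`, `mother`, `sex`,
#'   `founder`), and `topo` (indices of a deterministic founders-first
#'   topological order, ties broken lexicographically by ID).
#' @export
Pedigree <- function(family_id, id, father, mother, sex,
                     strict_parents = FALSE, rows = NULL) {
  id <- as.character(id)
  father <- as.character(father)
  mother <- as.character(mother)
  sex <- as.character(sex)
  if (is.null(rows)) rows <- seq_along(id)
  stopifnot(length(father) == length(id), length(mother) == length(id),
            length(sex) == length(id))
  if (anyDuplicated(id)) {
    d <- id[duplicated(id)][1L]
    stop("pedigree '", family_id, "': duplicate individual id '", d, "'")
  }
  bad_sex <- !sex %in% c("male", "female", "unknown")
  if (any(bad_sex))
    stop("pedigree '", family_id, "': invalid sex code at row ",
         rows[which(bad_sex)[1L]])

  # half-specified parentage
  half <- xor(is.na(father), is.na(mother))
  if (any(half))
    stop("pedigree '", family_id, "': individual '", id[which(half)[1L]],
         "' (row ", rows[which(half)[1L]],
         ") has exactly one parent specified; both or neither required")

  self_par <- !is.na(father) & (father == id | mother == id)
  if (any(self_par))
    stop("pedigree '", family_id, "': individual '", id[which(self_par)[1L]],
         "' (row ", rows[which(self_par)[1L]], ") is listed as its own parent")

  # parents referenced but absent
  pars <- unique(stats::na.omit(c(father, mother)))
  absent <- setdiff(pars, id)
  if (length(absent)) {
    if (strict_parents)
      stop("pedigree '", family_id, "': parent(s) ",
           paste0("'", absent, "'", collapse = ", "),
           " referenced but not listed as members")
    warning("pedigree '", family_id, "': adding ", length(absent),
            " parent(s) referenced but not listed (",
            paste0("'", absent, "'", collapse = ", "),
            ") as unknown-sex founders", call. = FALSE)
    id <- c(id, absent)
    father <- c(father, rep(NA_character_, length(absent)))
    mother <- c(mother, rep(NA_character_, length(absent)))
    sex <- c(sex, rep("unknown", length(absent)))
    rows <- c(rows, rep(NA_integer_, length(absent)))
  }

  n <- length(id)
  fi <- match(father, id)
  mi <- match(mother, id)
  founder <- is.na(fi)

  if (!any(founder))
    stop("pedigree '", family_id, "': no founders")

  # role-consistent sex; unknown sex only for founders
  is_father <- id %in% father[!is.na(father)]
  is_mother <- id %in% mother[!is.na(mother)]
  bad <- is_father & sex == "female"
  if (any(bad))
    stop("pedigree '", family_id, "': individual '", id[which(bad)[1L]],
         "' is female but referenced as a father")
  bad <- is_mother & sex == "male"
  if (any(bad))
    stop("pedigree '", family_id, "': individual '", id[which(bad)[1L]],
         "' is male but referenced as a mother")
  bad <- sex == "unknown" & !founder
  if (any(bad))
    stop("pedigree '", family_id, "': non-founder '", id[which(bad)[1L]],
         "' has unknown sex; unknown sex is allowed for founders only")

  topo <- ped_toposort(id, fi, mi, family_id)

  members <- data.frame(id = id, father = father, mother = mother,
                        sex = sex, founder = founder,
                        stringsAsFactors = FALSE)
  structure(list(family_id = as.character(family_id), members = members,
                 father_idx = fi, mother_idx = mi, topo = topo),
            class = "Pedigree")
}

# Kahn topological sort, founders first, lexicographic tie-break on id.
# Cycles (an individual among its own ancestors) are a structural error.
ped_toposort <- function(id, fi, mi, family_id) {
  n <- length(id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (j in seq_len(n)) {
    for (pidx in c(fi[j], mi[j])) {
      if (!is.na(pidx)) {
        indeg[j] <- indeg[j] + 1L
        children[[pidx]] <- c(children[[pidx]], j)
      }
    }
  }
  out <- integer(0)
  avail <- which(indeg == 0L)
  while (length(avail)) {
    avail <- avail[order(id[avail])]
    v <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) avail <- c(avail, ch)
    }
  }
  if (length(out) != n)
    stop("pedigree '", family_id,
         "': cyclic parentage involving individual(s) ",
         paste0("'", id[setdiff(seq_len(n), out)], "'", collapse = ", "))
  out
}

#' @export
print.Pedigree <- function(x, ...) {
  cat("Pedigree '", x$family_id, "': ", nrow(x$members), " members, ",
      sum(x$members$founder), " founders\n", sep = "")
  invisible(x)
}

#' @rdname Pedigree
#' @param ped a `Pedigree`.
#' @export
ped_ids <- function(ped) ped$members$id

#' @rdname Pedigree
#' @export
ped_founders <- function(ped) ped$members$id[ped$members$founder]

#' Read pedigrees from a LINKAGE-style ped or PLINK .fam file
#'
#' Whitespace-delimited columns: family, individual, father, mother, sex
#' (1 = male, 2 = female, 0 = unknown); trailing columns (e.g. the PLINK
#' phenotype column) are ignored.  The missing-parent code is `"0"`.
#'
#' @param path path to the file.
#' @param dialect `"linkage_ped"` or `"plink_fam"`; both are parsed
#'   identically (the distinction is documentary).
#' @inheritParams Pedigree
#' @return A named list with one `Pedigree` per `family_id`, in order of
#'   first appearance.
#' @export
read_pedigree <- function(path, dialect = c("linkage_ped", "plink_fam"),
                          strict_parents = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", fill = TRUE,
                           flush = TRUE)
  if (ncol(tab) < 5L)
    stop("pedigree file '", path, "': expected at least 5 columns, got ",
         ncol(tab))
  names(tab)[1:5] <- c("fam", "id", "father", "mother", "sex")
  tab$row <- seq_len(nrow(tab))
  sex_map <- c("1" = "male", "2" = "female", "0" = "unknown")
  bad <- !tab$sex %in% names(sex_map)
  if (any(bad))
    stop("pedigree file '", path, "': invalid sex code '",
         tab$sex[which(bad)[1L]], "' at row ", tab$row[which(bad)[1L]])
  fams <- unique(tab$fam)
  out <- lapply(fams, function(f) {
    sub <- tab[tab$fam == f, , drop = FALSE]
    Pedigree(family_id = f, id = sub$id,
             father = ifelse(sub$father == "0", NA_character_, sub$father),
             mother = ifelse(sub$mother == "0", NA_character_, sub$mother),
             sex = unname(sex_map[sub$sex]),
             strict_parents = strict_parents, rows = sub$row)
  })
  names(out) <- fams
  out
}

#' Write pedigrees to a LINKAGE-style ped file
#'
#' @param peds list of `Pedigree` objects.
#' @param path output path.
#' @export
write_pedigree <- function(peds, path) {
  rows <- do.call(rbind, lapply(peds, function(p) {
    m <- p$members
    data.frame(fam = p$family_id, id = m$id,
               father = ifelse(is.na(m$father), "0", m$father),
               mother = ifelse(is.na(m$mother), "0", m$mother),
               sex = c(male = "1", female = "2", unknown = "0")[m$sex],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}
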