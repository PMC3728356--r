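#' Construct and validate a pedigree
#'
#' A pedigree holds the family structure used by the linkage engine: one row
#' per individual with parent links, sex, disease phenotype and an optional
#' flag marking individuals younger than the family's average age of onset.
#' Flagged individuals are treated as phenotype-unknown in all likelihoods,
#' because a young carrier may simply not have presented yet.
#'
#' Validation enforces: unique ids; both parents present or both absent;
#' parent ids resolving within the family; father male / mother female;
#' acyclic ancestry; and absence of marriage/consanguinity loops (pedigrees
#' with loops are rejected rather than loop-broken).
#'
#' @param members data.frame with columns `id`, `father_id`, `mother_id`
#'   (`NA` for founders), `sex` (`"male"`/`"female"`), `phenotype`
#'   (`"affected"`/`"unaffected"`/`"unknown"`) and optionally
#'   `below_onset_age` (logical, default `FALSE`).
#' @param family_id single string naming the family.
#' @return An object of class `pedigree`: a list with elements `family_id`
#'   and `members` (the validated data.frame, with a founders-first
#'   topological ordering stored in `attr(, "topo_order")`).
#' @examples
#' ped <- pedigree(data.frame(
#'   id = c("p1", "p2", "c1"),
#'   father_id = c(NA, NA, "p1"),
#'   mother_id = c(NA, NA, "p2"),
#'   sex = c("male", "female", "female"),
#'   phenotype = c("affected", "unaffected", "affected")
#' ))
#' summary(ped)
#' @export
pedigree <- function(members, family_id = "FAM1") {
  stopifnot(is.data.frame(members), is_string(family_id))
  stopifnot_cols(members, c("id", "father_id", "mother_id", "sex", "phenotype"),
                 "pedigree member table")
  m <- members
  m$id <- as.character(m$id)
  m$father_id <- as.character(m$father_id)
  m$mother_id <- as.character(m$mother_id)
  m$father_id[m$father_id %in% c("0", "")] <- NA_character_
  m$mother_id[m$mother_id %in% c("0", "")] <- NA_character_
  m$sex <- as.character(m$sex)
  m$phenotype <- as.character(m$phenotype)
  if (is.null(m$below_onset_age)) m$below_onset_age <- FALSE
  m$below_onset_age <- as.logical(m$below_onset_age)

  dup <- m$id[duplicated(m$id)]
  if (length(dup))
    stop_lx("lx_duplicate_id", "duplicate individual id(s): %s (family %s)",
            paste(unique(dup), collapse = ", "), family_id)
  if (!all(m$sex %in% c("male", "female")))
    stop_lx("lx_bad_sex", "sex must be 'male' or 'female' (row %d)",
            which(!m$sex %in% c("male", "female"))[1])
  if (!all(m$phenotype %in% c("affected", "unaffected", "unknown")))
    stop_lx("lx_bad_phenotype",
            "phenotype must be affected/unaffected/unknown (row %d)",
            which(!m$phenotype %in% c("affected", "unaffected", "unknown"))[1])

  half <- xor(is.na(m$father_id), is.na(m$mother_id))
  if (any(half))
    stop_lx("lx_single_parent",
            "individual %s has exactly one parent recorded; both or neither required",
            m$id[which(half)[1]])

  for (col in c("father_id", "mother_id")) {
    bad <- !is.na(m[[col]]) & !(m[[col]] %in% m$id)
    if (any(bad))
      stop_lx("lx_unresolved_parent",
              "individual %s names %s '%s' who is not in the family",
              m$id[which(bad)[1]], sub("_id", "", col), m[[col]][which(bad)[1]])
  }
  fa_sex <- m$sex[match(m$father_id, m$id)]
  mo_sex <- m$sex[match(m$mother_id, m$id)]
  if (any(!is.na(fa_sex) & fa_sex != "male"))
    stop_lx("lx_parent_sex", "father of %s is not male",
            m$id[which(!is.na(fa_sex) & fa_sex != "male")[1]])
  if (any(!is.na(mo_sex) & mo_sex != "female"))
    stop_lx("lx_parent_sex", "mother of %s is not female",
            m$id[which(!is.na(mo_sex) & mo_sex != "female")[1]])

  topo <- topo_order_ids(m)           # errors on cyclic ancestry
  ped <- structure(list(family_id = family_id, members = m),
                   class = "pedigree")
  check_loop_free(ped)                # errors on marriage/consanguinity loops
  attr(ped$members, "topo_order") <- topo
  ped
}

# Kahn's algorithm; founders first.  Cyclic ancestry (e.g. an individual
# listed as its own ancestor) leaves unresolved rows behind.
topo_order_ids <- function(m) {
  ids <- m$id
  placed <- character(0)
  remaining <- ids
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      r <- m[m$id == i, ]
      (is.na(r$father_id) || r$father_id %in% placed) &&
        (is.na(r$mother_id) || r$mother_id %in% placed)
    }, logical(1))]
    if (!length(ready)) break
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining))
    stop_lx("lx_cyclic_ancestry",
            "cyclic ancestry involving individual(s): %s",
            paste(remaining, collapse = ", "))
  placed
}

#' @export
print.pedigree <- function(x, ...) {
  m <- x$members
  cat(sprintf("Pedigree %s: %d members (%d affected, %d unaffected, %d unknown; %d below onset age)\n",
              x$family_id, nrow(m),
              sum(m$phenotype == "affected"),
              sum(m$phenotype == "unaffected"),
              sum(m$phenotype == "unknown"),
              sum(m$below_onset_age)))
  invisible(x)
}

#' @export
summary.pedigree <- function(object, ...) {
  m <- object$members
  founders <- is.na(m$father_id)
  out <- list(
    family_id = object$family_id,
    n = nrow(m),
    n_founders = sum(founders),
    n_affected = sum(m$phenotype == "affected"),
    n_unaffected = sum(m$phenotype == "unaffected"),
    n_unknown = sum(m$phenotype == "unknown"),
    n_below_onset = sum(m$below_onset_age),
    n_generations = pedigree_depth(m)
  )
  class(out) <- "summary.pedigree"
  out
}

#' @export
print.summary.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree %s\n", x$family_id))
  cat(sprintf("  members:        %d (%d founders, %d generations)\n",
              x$n, x$n_founders, x$n_generations))
  cat(sprintf("  phenotypes:     %d affected / %d unaffected / %d unknown\n",
              x$n_affected, x$n_unaffected, x$n_unknown))
  cat(sprintf("  below onset:    %d (treated as unknown in likelihoods)\n",
              x$n_below_onset))
  invisible(x)
}

pedigree_depth <- function(m) {
  depth <- setNames(rep(NA_integer_, nrow(m)), m$id)
  topo <- attr(m, "topo_order") %||% topo_order_ids(m)
  for (i in topo) {
    r <- m[m$id == i, ]
    depth[i] <- if (is.na(r$father_id)) 1L
                else max(depth[r$father_id], depth[r$mother_id]) + 1L
  }
  max(depth)
}

#' Effective phenotype used by the likelihood
#'
#' Individuals flagged as younger than the average onset age are scored as
#' phenotype-unknown regardless of their recorded phenotype, since absence of
#' disease in a pre-onset carrier is uninformative.
#'
#' @param ped a [pedigree()].
#' @return named character vector (`affected`/`unaffected`/`unknown`) by id.
#' @export
effective_phenotype <- function(ped) {
  m <- ped$members
  ph <- ifelse(m$below_onset_age, "unknown", m$phenotype)
  setNames(ph, m$id)
}

#' Read a pedigree from a LINKAGE-style PED file
#'
#' Whitespace-delimited columns: family id, individual id, father id, mother
#' id (0 = absent), sex (1 = male, 2 = female), phenotype (2 = affected,
#' 1 = unaffected, 0 = unknown), and an optional seventh column flagging
#' individuals below the average onset age (0/1; absent means 0).  Lines
#' starting with `#` are comments.
#'
#' @param path file path.
#' @return a validated [pedigree()].
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path))
    stop_lx("lx_missing_file", "pedigree file not found: %s", path)
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!ncol(raw) %in% c(6L, 7L))
    stop_lx("lx_bad_ped_format",
            "expected 6 or 7 whitespace-delimited columns, got %d", ncol(raw))
  names(raw)[1:6] <- c("famid", "id", "father_id", "mother_id", "sex", "pheno")
  fam <- unique(raw$famid)
  if (length(fam) != 1L)
    stop_lx("lx_bad_ped_format", "file contains %d family ids; expected one",
            length(fam))
  sex <- c("1" = "male", "2" = "female")[raw$sex]
  if (anyNA(sex))
    stop_lx("lx_bad_sex", "sex code must be 1 or 2 (row %d)",
            which(is.na(sex))[1])
  phen <- c("2" = "affected", "1" = "unaffected", "0" = "unknown")[raw$pheno]
  if (anyNA(phen))
    stop_lx("lx_bad_phenotype", "phenotype code must be 0, 1 or 2 (row %d)",
            which(is.na(phen))[1])
  flag <- if (ncol(raw) == 7L) raw[[7]] == "1" else FALSE
  pedigree(data.frame(id = raw$id, father_id = raw$father_id,
                      mother_id = raw$mother_id, sex = unname(sex),
                      phenotype = unname(phen), below_onset_age = flag,
                      stringsAsFactors = FALSE),
           family_id = fam)
}

#' Write a pedigree in LINKAGE-style PED format
#'
#' Inverse of [read_pedigree()]: the written file reads back to an identical
#' pedigree (all fields round-trip).
#'
#' @param ped a [pedigree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  m <- ped$members
  out <- data.frame(
    famid = ped$family_id,
    id = m$id,
    father = ifelse(is.na(m$father_id), "0", m$father_id),
    mother = ifelse(is.na(m$mother_id), "0", m$mother_id),
    sex = ifelse(m$sex == "male", 1L, 2L),
    pheno = c(affected = 2L, unaffected = 1L, unknown = 0L)[m$phenotype],
    flag = as.integer(m$below_onset_age)
  )
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# --- nuclear-family decomposition -------------------------------------------

# Families (couples + children) and the individual->family incidence used by
# both the peeling engine and the loop check.  Returns list(fams, ind2fams)
# with indices into ped$members.
nuclear_families <- function(ped) {
  m <- ped$members
  idx <- setNames(seq_len(nrow(m)), m$id)
  kids <- which(!is.na(m$father_id))
  key <- paste(m$father_id[kids], m$mother_id[kids], sep = "\r")
  fams <- lapply(split(kids, key), function(ch) {
    list(fa = idx[[m$father_id[ch[1]]]],
         mo = idx[[m$mother_id[ch[1]]]],
         kids = unname(ch))
  })
  fams <- unname(fams)
  ind2fams <- vector("list", nrow(m))
  for (f in seq_along(fams)) {
    for (i in c(fams[[f]]$fa, fams[[f]]$mo, fams[[f]]$kids))
      ind2fams[[i]] <- c(ind2fams[[i]], f)
  }
  list(fams = fams, ind2fams = ind2fams)
}

# The pedigree is loop-free iff the bipartite graph (families x shared
# individuals) is a forest.  Marriage or consanguinity loops create cycles.
check_loop_free <- function(ped) {
  nf <- nuclear_families(ped)
  n_fam <- length(nf$fams)
  if (n_fam == 0L) return(invisible(TRUE))
  # bipartite nodes: families 1..n_fam, then connector individuals
  connectors <- which(lengths(nf$ind2fams) > 1L)
  adj <- vector("list", n_fam + length(connectors))
  for (ci in seq_along(connectors)) {
    i <- connectors[ci]
    cnode <- n_fam + ci
    for (f in nf$ind2fams[[i]]) {
      adj[[f]] <- c(adj[[f]], cnode)
      adj[[cnode]] <- c(adj[[cnode]], f)
    }
  }
  seen <- rep(FALSE, length(adj))
  for (start in seq_along(adj)) {
    if (seen[start]) next
    # iterative DFS keeping the edge we arrived by
    stack <- list(c(start, 0L))
    seen[start] <- TRUE
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      node <- top[1]; parent <- top[2]
      skipped_parent <- FALSE
      for (nb in adj[[node]]) {
        if (nb == parent && !skipped_parent) { skipped_parent <- TRUE; next }
        if (seen[nb])
          stop_lx("lx_pedigree_loop",
                  "pedigree %s contains a marriage/consanguinity loop; looped pedigrees are not supported",
                  ped$family_id)
        seen[nb] <- TRUE
        stack[[length(stack) + 1L]] <- c(nb, node)
      }
    }
  }
  invisible(TRUE)
}

#' Count phase-known (unambiguous) marker transmissions
#'
#' A parent-to-child meiosis is counted when the marker allele transmitted by
#' that parent can be determined without ambiguity from the child's genotype,
#' the parent's genotype (if typed) and the other parent's genotype (if
#' typed).  Children with missing genotypes contribute nothing.
#'
#' @param ped a [pedigree()].
#' @param gt a [genotype_table()] validated against `ped`.
#' @return integer count of unambiguous transmissions.
#' @export
count_phase_known_meioses <- function(ped, gt) {
  m <- ped$members
  calls <- gt$calls
  get_call <- function(id) {
    r <- calls[calls$id == id, ]
    if (!nrow(r) || is.na(r$allele1[1])) NULL else c(r$allele1[1], r$allele2[1])
  }
  n <- 0L
  for (i in which(!is.na(m$father_id))) {
    cg <- get_call(m$id[i])
    if (is.null(cg)) next
    fg <- get_call(m$father_id[i])
    mg <- get_call(m$mother_id[i])
    # ordered assignments (x from father, y from mother)
    cand <- unique(rbind(c(cg[1], cg[2]), c(cg[2], cg[1])))
    ok <- apply(cand, 1, function(a) {
      (is.null(fg) || a[1] %in% fg) && (is.null(mg) || a[2] %in% mg)
    })
    cons <- cand[ok, , drop = FALSE]
    if (!nrow(cons)) next                      # Mendelian-inconsistent: skip
    if (length(unique(cons[, 1])) == 1L) n <- n + 1L
    if (length(unique(cons[, 2])) == 1L) n <- n + 1L
  }
  n
}
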