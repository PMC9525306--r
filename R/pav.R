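#' Presence/absence-variation (PAV) matrix
#'
#' The pan-genome's central object: a logical orthogroup x accession matrix
#' plus a subpopulation label per accession. Constructed directly or via
#' [build_pav_matrix()].
#'
#' @param presence Logical matrix with orthogroup rownames and accession
#'   colnames; every row must have at least one `TRUE`.
#' @param subpop Named character vector mapping accession to subpopulation;
#'   accessions without a label get the sentinel `"unassigned"`.
#' @return A `pav_matrix` object.
#' @export
pav_matrix <- function(presence, subpop = NULL) {
  if (!is.matrix(presence) || !is.logical(presence)) {
    abort("`presence` must be a logical matrix")
  }
  if (is.null(rownames(presence)) || is.null(colnames(presence))) {
    abort("`presence` must have orthogroup rownames and accession colnames")
  }
  if (anyDuplicated(rownames(presence)) || anyDuplicated(colnames(presence))) {
    abort("duplicate orthogroup or accession ids")
  }
  if (nrow(presence) > 0 && any(rowSums(presence) == 0)) {
    abort("every orthogroup row must have at least one presence")
  }
  sp <- setNames(rep("unassigned", ncol(presence)), colnames(presence))
  if (!is.null(subpop)) {
    known <- intersect(names(subpop), names(sp))
    sp[known] <- subpop[known]
  }
  structure(list(presence = presence, subpop = sp), class = "pav_matrix")
}

#' @export
print.pav_matrix <- function(x, ...) {
  cat(sprintf("<pav_matrix> %d orthogroups x %d accessions (%s)\n",
              nrow(x$presence), ncol(x$presence),
              paste(sprintf("%s: %d", names(table(x$subpop)), table(x$subpop)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
as_tibble.pav_matrix <- function(x, ...) {
  bind_cols(tibble(orthogroup_id = rownames(x$presence)),
            as_tibble(x$presence, .name_repair = "minimal"))
}

#' @describeIn pav_matrix long-format tidy view (`orthogroup_id,
#'   accession_id, present`).
#' @param x,... `pav_matrix` and ignored arguments.
#' @export
tidy.pav_matrix <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(-"orthogroup_id", names_to = "accession_id",
                        values_to = "present")
}

#' Build a PAV matrix from an orthogroup membership table
#'
#' Transcribes an OrthoFinder-style table (one row per orthogroup, one column
#' per accession, cells holding comma-separated gene ids or empty) into a
#' logical presence matrix: present iff the cell is non-empty. Orthogroups
#' present in no requested accession are dropped with a warning.
#'
#' @param orthogroup_table Tibble as returned by [read_orthogroup_tsv()] or
#'   `simulate_pangenome()$orthogroups`; first column is the orthogroup id.
#' @param accessions Accessions to keep (default: all non-id columns).
#' @param subpop Optional tibble `accession_id, subpop` or named vector.
#' @return A [pav_matrix()].
#' @export
build_pav_matrix <- function(orthogroup_table, accessions = NULL, subpop = NULL) {
  id_col <- names(orthogroup_table)[1]
  accessions <- accessions %||% setdiff(names(orthogroup_table), id_col)
  missing_acc <- setdiff(accessions, names(orthogroup_table))
  if (length(missing_acc) > 0) {
    abort(sprintf("accession column(s) absent from orthogroup table: %s",
                  paste(missing_acc, collapse = ", ")))
  }
  cells <- as.matrix(orthogroup_table[accessions])
  cells[is.na(cells)] <- ""
  presence <- cells != ""
  rownames(presence) <- orthogroup_table[[id_col]]
  empty <- rowSums(presence) == 0
  if (any(empty)) {
    warn(sprintf("dropping %d orthogroup(s) present in no accession", sum(empty)))
    presence <- presence[!empty, , drop = FALSE]
  }
  if (is.data.frame(subpop)) {
    subpop <- setNames(subpop$subpop, subpop$accession_id)
  }
  pav_matrix(presence, subpop)
}

#' Classify orthogroups as core or dispensable
#'
#' An orthogroup is core iff it is present in at least `threshold` of the
#' accessions, i.e. `n_present / n_accessions >= threshold` as an exact
#' fraction test with no integer pre-rounding (for 251 accessions at the
#' default 0.95 the boundary is 239 present = core, 238 = dispensable).
#' Everything else is dispensable, so the two classes partition the matrix.
#'
#' @param pav A [pav_matrix()].
#' @param threshold Core presence fraction in `(0, 1]`; default 0.95.
#' @return Tibble `orthogroup_id, n_present, frequency, class`.
#' @export
classify_core_dispensable <- function(pav, threshold = 0.95) {
  stopifnot(inherits(pav, "pav_matrix"))
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1]")
  n <- ncol(pav$presence)
  k <- unname(rowSums(pav$presence))
  tibble(orthogroup_id = rownames(pav$presence),
         n_present = as.integer(k),
         frequency = if (n > 0) k / n else numeric(0),
         class = ifelse(k / n >= threshold, "core", "dispensable"))
}

#' Pan- and core-genome rarefaction curves
#'
#' Randomizes the accession order `n_orders` times and, at each step `k` of
#' each ordering, counts the pan size (union of orthogroups over the first
#' `k` accessions) and the core size (their intersection). In `"nonprivate"`
#' mode the matrix is first restricted, once on the full input panel, to
#' orthogroups present in at least two accessions.
#'
#' @param pav A [pav_matrix()].
#' @param n_orders Number of random orderings (>= 1); default 500.
#' @param seed Integer seed.
#' @param gene_set_mode `"all"` or `"nonprivate"`.
#' @return A `pan_rarefaction` tibble: `count_kind` (pan/core),
#'   `n_accessions`, `mean_count, sd_count, min_count, max_count` per step.
#' @export
rarefaction_curves <- function(pav, n_orders = 500, seed = 1L,
                               gene_set_mode = c("all", "nonprivate")) {
  stopifnot(inherits(pav, "pav_matrix"))
  gene_set_mode <- match.arg(gene_set_mode)
  if (n_orders < 1) abort("`n_orders` must be >= 1")
  set.seed(.check_seed(seed))

  M <- pav$presence
  if (gene_set_mode == "nonprivate") {
    M <- M[rowSums(M) >= 2, , drop = FALSE]
  }
  N <- ncol(M)
  pan <- matrix(0L, n_orders, N)
  core <- matrix(0L, n_orders, N)
  all_true <- rowSums(M) == N
  for (o in seq_len(n_orders)) {
    idx <- sample.int(N)
    Mo <- M[, idx, drop = FALSE] * 1
    # pan: step of each row's first presence; core: step of first absence
    fp <- max.col(Mo, ties.method = "first")
    pan[o, ] <- cumsum(tabulate(fp, N))
    ff <- max.col(1 - Mo, ties.method = "first")     # first absence position
    ff[all_true] <- N + 1L                           # never absent
    core[o, ] <- rev(cumsum(rev(tabulate(ff, N + 1L))))[-1]  # rows with ff > k
  }
  summarize_steps <- function(mat, kind) {
    tibble(count_kind = kind, n_accessions = seq_len(N),
           mean_count = colMeans(mat),
           sd_count = apply(mat, 2, sd),
           min_count = apply(mat, 2, min),
           max_count = apply(mat, 2, max))
  }
  out <- bind_rows(summarize_steps(pan, "pan"), summarize_steps(core, "core"))
  structure(out,
            class = c("pan_rarefaction", class(out)),
            n_orders = n_orders, gene_set_mode = gene_set_mode,
            per_order = list(pan = pan, core = core))
}

#' @export
tidy.pan_rarefaction <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @export
glance.pan_rarefaction <- function(x, ...) {
  last <- x[x$n_accessions == max(x$n_accessions), ]
  tibble(n_accessions = max(x$n_accessions),
         n_orders = attr(x, "n_orders"),
         gene_set_mode = attr(x, "gene_set_mode"),
         pan_final = last$mean_count[last$count_kind == "pan"],
         core_final = last$mean_count[last$count_kind == "core"])
}

#' Pairwise PAV divergence between accessions
#'
#' For each pair of accessions drawn across (or within) the given groups,
#' counts the orthogroups that differ (the symmetric difference of the two
#' presence sets) and reports the ratio to the union of the two sets, so the
#' ratio is 0 for identical gene content and 1 for disjoint content. Pairs
#' involving an accession with zero genes have an undefined ratio; they are
#' flagged, excluded from the mean and counted.
#'
#' @param pav A [pav_matrix()].
#' @param group_a Accession ids (or a subpopulation name) for the first group.
#' @param group_b Optional second group; if `NULL`, all unordered pairs
#'   within `group_a` are used.
#' @return A `pav_divergence` object: per-pair tibble plus summary; see
#'   [tidy()] / [glance()].
#' @export
pairwise_pav_divergence <- function(pav, group_a, group_b = NULL) {
  stopifnot(inherits(pav, "pav_matrix"))
  resolve <- function(g) {
    if (length(g) == 1 && g %in% pav$subpop && !(g %in% colnames(pav$presence))) {
      return(names(pav$subpop)[pav$subpop == g])
    }
    miss <- setdiff(g, colnames(pav$presence))
    if (length(miss) > 0) {
      abort(sprintf("unknown accession(s): %s", paste(miss, collapse = ", ")))
    }
    g
  }
  a <- resolve(group_a)
  within <- is.null(group_b)
  b <- if (within) a else resolve(group_b)
  if (length(a) == 0 || length(b) == 0) abort("groups must be non-empty")

  P <- pav$presence * 1L
  sizes <- colSums(P)
  inter <- crossprod(P[, a, drop = FALSE], P[, b, drop = FALSE])
  pairs <- as_tibble(as.table(inter), .name_repair = "minimal") |>
    setNames(c("accession_a", "accession_b", "n_shared")) |>
    mutate(accession_a = as.character(.data$accession_a),
           accession_b = as.character(.data$accession_b))
  if (within) {
    pairs <- pairs[match(pairs$accession_a, a) < match(pairs$accession_b, b), ]
  } else {
    pairs <- pairs[pairs$accession_a != pairs$accession_b, ]
  }
  pairs <- pairs |>
    mutate(n_a = unname(sizes[.data$accession_a]),
           n_b = unname(sizes[.data$accession_b]),
           n_union = .data$n_a + .data$n_b - .data$n_shared,
           n_differing = .data$n_a + .data$n_b - 2 * .data$n_shared,
           ratio = ifelse(.data$n_union > 0,
                          .data$n_differing / .data$n_union, NA_real_))
  n_excl <- sum(is.na(pairs$ratio))
  if (n_excl > 0) {
    warn(sprintf("%d pair(s) with an empty union excluded from the mean ratio",
                 n_excl))
  }
  structure(list(pairs = pairs,
                 mean_ratio = mean(pairs$ratio, na.rm = TRUE),
                 mean_differing = mean(pairs$n_differing[!is.na(pairs$ratio)]),
                 n_pairs = nrow(pairs), n_excluded = n_excl),
            class = "pav_divergence")
}

#' @export
print.pav_divergence <- function(x, ...) {
  cat(sprintf("<pav_divergence> %d pairs; mean PAV ratio %.4f (mean differing %.1f; %d excluded)\n",
              x$n_pairs, x$mean_ratio, x$mean_differing, x$n_excluded))
  invisible(x)
}

#' @export
tidy.pav_divergence <- function(x, ...) x$pairs

#' @export
glance.pav_divergence <- function(x, ...) {
  tibble(mean_ratio = x$mean_ratio, mean_differing = x$mean_differing,
         n_pairs = x$n_pairs, n_excluded = x$n_excluded)
}

#' Assign orthogroups to taxonomic sharing levels
#'
#' Groups orthogroups into four hierarchical levels by which rice
#' subpopulations carry them, applying each rule in order so earlier levels
#' exclude later ones: level I = present in both Or (Asian wild) and Ob
#' (African wild); II = present in both Or and Os (Osi or Osj), excluding I;
#' III = present in both Og and Ob, excluding I; IV = present in both Osi and
#' Osj, excluding I and II. Orthogroups fitting no level (e.g. present only
#' in Osi and Og) are `"undetermined"`.
#'
#' @param pav A [pav_matrix()] whose subpopulation labels include `Or`, `Ob`,
#'   `Og`, `Osi` and `Osj`.
#' @return Tibble `orthogroup_id, level` with level in
#'   `I, II, III, IV, undetermined`.
#' @export
assign_taxon_levels <- function(pav) {
  stopifnot(inherits(pav, "pav_matrix"))
  need <- c("Or", "Ob", "Og", "Osi", "Osj")
  miss <- setdiff(need, unique(pav$subpop))
  if (length(miss) > 0) {
    abort(sprintf("missing required subpopulation(s): %s",
                  paste(miss, collapse = ", ")))
  }
  in_pop <- function(p) {
    cols <- names(pav$subpop)[pav$subpop == p]
    rowSums(pav$presence[, cols, drop = FALSE]) > 0
  }
  or <- in_pop("Or"); ob <- in_pop("Ob"); og <- in_pop("Og")
  osi <- in_pop("Osi"); osj <- in_pop("Osj")
  os <- osi | osj
  # assigned in order I -> IV: each level excludes the earlier ones
  level <- dplyr::case_when(
    or & ob ~ "I",
    or & os ~ "II",
    og & ob ~ "III",
    osi & osj ~ "IV",
    TRUE ~ "undetermined")
  tibble(orthogroup_id = rownames(pav$presence), level = level)
}
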