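#' Group recent human paralogues into ancestral units
#'
#' Genes duplicated on the human lineage since the mammalian
#' divergence would confound per-gene conservation counts: every
#' genome not sharing the duplication would look "changed" relative to
#' human. Such recent in-paralogues are therefore grouped, their
#' ancestral copy number of 1 is assumed, and the group is compared
#' with the copy number in each other species: the group's status in a
#' species is `one2one` when the species carries exactly one distinct
#' orthologue of the group, `one2many` when more than one, and `none`
#' when zero.
#'
#' Because the three-state per-gene status cannot express "how many
#' orthologues", this operation works from orthologue *pairs*: one row
#' per (human gene, species, orthologue gene).
#'
#' @param pairs Data.frame with columns `human_gene`, `species`,
#'   `ortholog_id` (one row per orthologue pair; genes with no
#'   orthologue in a species simply have no row there).
#' @param groups Data.frame with columns `gene_id`, `group_id` mapping
#'   human genes to recent-paralogue groups; genes absent from the map
#'   form singleton groups. A gene mapped to two groups is an error.
#' @param species_list Species universe (13 names by default).
#' @return An orthology profile data.frame (as from
#'   [read_orthology_table()]) with one row per group: `unit_id` is
#'   the group id, `group_members` lists the human genes.
#' @export
group_recent_paralogues <- function(pairs, groups = NULL,
                                    species_list = mammal_species_13()) {
  need <- c("human_gene", "species", "ortholog_id")
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols))
    stop("pairs is missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(pairs$species), species_list)
  if (length(bad))
    stop("species not in species_list: ", bad[1])
  genes <- unique(pairs$human_gene)
  if (is.null(groups))
    groups <- data.frame(gene_id = character(0), group_id = character(0))
  dup <- groups$gene_id[duplicated(groups$gene_id)]
  if (length(dup))
    stop("gene mapped to two paralogue groups: ", dup[1])
  unit <- groups$group_id[match(genes, groups$gene_id)]
  unit[is.na(unit)] <- genes[is.na(unit)]  # singleton groups
  unit_of_gene <- stats::setNames(unit, genes)
  units <- unique(unit)
  # distinct orthologues per (unit, species)
  pu <- unique(data.frame(unit = unit_of_gene[pairs$human_gene],
                          species = pairs$species,
                          ortholog = pairs$ortholog_id,
                          stringsAsFactors = FALSE))
  counts <- table(factor(pu$unit, levels = units),
                  factor(pu$species, levels = species_list))
  status <- matrix("none", nrow = length(units), ncol = length(species_list),
                   dimnames = dimnames(counts))
  status[counts == 1] <- "one2one"
  status[counts > 1] <- "one2many"
  profiles <- data.frame(unit_id = units, stringsAsFactors = FALSE)
  for (sp in species_list) profiles[[sp]] <- unname(status[, sp])
  profiles$group_members <- I(unname(split(genes, factor(unit, levels = units))))
  attr(profiles, "species") <- species_list
  profiles
}

#' Tally conservation of orthology profiles
#'
#' For each unit (gene or recent-paralogue group), counts the species
#' where the copy number is unchanged (one-to-one orthology), where a
#' duplication has occurred (one-to-many) and where no orthologue is
#' detected (presumed loss). A unit is *conserved* when its copy
#' number is unchanged in all species surveyed. Intended for genes
#' inferred present in the mammalian common ancestor; non-ancestral
#' genes should be excluded upstream.
#'
#' @param profiles Orthology profile data.frame (from
#'   [read_orthology_table()], [group_recent_paralogues()] or
#'   [simulate_orthology()]).
#' @return Data.frame with `unit_id`, `n_unchanged`, `n_duplicated`,
#'   `n_missing`, `conserved`; the three counts always sum to the
#'   number of species.
#' @export
summarize_profiles <- function(profiles) {
  species <- attr(profiles, "species")
  if (is.null(species))
    stop("profiles lacks a 'species' attribute")
  st <- as.matrix(profiles[, species, drop = FALSE])
  bad <- setdiff(unique(as.vector(st)), .orthology_statuses)
  if (length(bad))
    stop("unknown orthology status token: ", bad[1],
         " (many2many must be resolved by paralogue grouping)")
  out <- data.frame(unit_id = profiles$unit_id,
                    n_unchanged = rowSums(st == "one2one"),
                    n_duplicated = rowSums(st == "one2many"),
                    n_missing = rowSums(st == "none"),
                    stringsAsFactors = FALSE)
  out$conserved <- out$n_unchanged == length(species)
  rownames(out) <- NULL
  out
}

#' Conservation distributions by dosage class
#'
#' Joins per-gene conservation summaries to dosage-class assignments
#' and reports, per class, the quartiles and medians of the
#' unchanged/duplicated/missing species counts and the number of
#' fully conserved genes; also runs the scale comparison
#' (Fligner-Killeen on `n_unchanged` across classes) and the
#' chi-squared test on the conserved-by-class contingency table.
#'
#' @param summaries A [summarize_profiles()] result keyed by gene id.
#' @param assignments An [assign_classes()] result on the same gene
#'   universe. Classes with no scored genes are omitted with a
#'   warning; `unclassified` genes are excluded.
#' @return List with `per_class` (data.frame), `fligner` (result of
#'   [fligner_killeen()], `NULL` if fewer than 2 usable classes) and
#'   `chi2` (result of [chi2_with_residuals()] on conserved x class,
#'   `NULL` if degenerate).
#' @export
conservation_by_class <- function(summaries, assignments) {
  merged <- merge(assignments[assignments$label != "unclassified",
                              c("gene_id", "label")],
                  summaries, by.x = "gene_id", by.y = "unit_id")
  present <- intersect(.class_labels, unique(merged$label))
  absent <- setdiff(setdiff(.class_labels, "unclassified"), present)
  if (length(absent))
    warning("classes with no scored genes omitted: ",
            paste(absent, collapse = ", "))
  q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  per_class <- do.call(rbind, lapply(present, function(lb) {
    s <- merged[merged$label == lb, ]
    qu <- q(s$n_unchanged); qd <- q(s$n_duplicated); qm <- q(s$n_missing)
    data.frame(label = lb, n_genes = nrow(s),
               unchanged_q1 = qu[1], unchanged_median = qu[2],
               unchanged_q3 = qu[3],
               duplicated_median = qd[2], missing_median = qm[2],
               n_conserved = sum(s$conserved),
               stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL
  fk <- NULL
  groups <- split(merged$n_unchanged, merged$label)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(groups) >= 2)
    fk <- fligner_killeen(groups)
  chi2 <- NULL
  tab <- table(factor(merged$conserved, levels = c(FALSE, TRUE)),
               merged$label)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) == 2 && ncol(tab) >= 2 && all(rowSums(tab) > 0))
    chi2 <- chi2_with_residuals(unclass(tab))
  list(per_class = per_class, fligner = fk, chi2 = chi2)
}
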