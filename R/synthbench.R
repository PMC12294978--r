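# Synthetic DrugBank-shaped benchmark. Drugs are assembled from small alkyl /
# aryl backbones decorated with one functional group (carboxylic acid,
# primary amine, hydroxyl, or halide); a configurable fraction are emitted as
# E/Z isomer pairs around a C=C double bond, which share an identical 2D
# graph but different conformer geometry. Interaction labels follow a known
# rule book so that learnability, ablation direction and stereochemistry
# sensitivity are decidable offline:
#   type 1  both drugs carry a carboxylic acid
#   type 2  one carries an acid, the other a primary amine
#   type 3  one is the cis member of an isomer pair, the other carries a
#           hydroxyl (the stereo rule: its 2D inputs cannot separate it)
# Pairs firing no rule are non-edges and omitted, matching the
# positives-only shape of curated DDI triple tables.

#' Specification for the synthetic benchmark
#'
#' @param n_drugs Library size (>= 4).
#' @param n_types Number of interaction types emitted (1-3 of the rule book).
#' @param label_noise Probability that a label is flipped to a different
#'   type, in `[0, 0.5)`.
#' @param stereo_fraction Fraction of drugs emitted as E/Z isomer pairs.
#' @param seed Generator seed.
#' @param max_triples Cap on emitted triples (sampled down when exceeded,
#'   keeping every type represented); synthetic libraries are quadratic in
#'   pairs, so desk-scale runs cap the table.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_drugs = 200L, n_types = 3L, label_noise = 0.05,
                       stereo_fraction = 0.2, seed = 1L, max_triples = 1500L) {
  stopifnot(n_drugs >= 4, n_types >= 1, n_types <= 3,
            label_noise >= 0, label_noise < 0.5,
            stereo_fraction >= 0, stereo_fraction <= 1)
  structure(list(n_drugs = as.integer(n_drugs), n_types = as.integer(n_types),
                 label_noise = label_noise, stereo_fraction = stereo_fraction,
                 seed = as.integer(seed), max_triples = max_triples),
            class = "synth_spec")
}

# functional-group decorations appended to a backbone carbon
SYNTH_GROUPS <- c(acid = "C(=O)O", amine = "N", hydroxyl = "O", halide = "Cl")

# small saturated/aromatic backbones; the group is appended at the end
SYNTH_BACKBONES <- c("CC", "CCC", "CCCC", "CC(C)C", "CCCCC", "CC(C)CC",
                     "CCCCCC", "CCOC", "CCCOC", "CC(C)OC", "CCSC", "CCCSC",
                     "c1ccccc1C", "c1ccc(C)cc1C", "Cc1ccccc1CC",
                     "c1ccncc1C", "CCc1ccccc1C", "C1CCCCC1C", "C1CCCC1C",
                     "C1CCCCC1CC")

# E/Z scaffold: left/right substituents around a stereo double bond; halide
# substituents keep the stereo drugs out of the acid/amine rules
SYNTH_STEREO_LEFT <- c("F", "Cl", "Br", "CC", "CCC", "C(C)C")
SYNTH_STEREO_RIGHT <- c("CC", "CCC", "CCCC", "CC(C)C", "CCl", "CBr", "COC")

#' Generate the synthetic drug library
#'
#' Deterministic per seed; every emitted SMILES parses. Stereo drugs come in
#' cis/trans pairs whose 2D molecular graphs are bit-identical.
#'
#' @param spec A [synth_spec()].
#' @return A registry tibble with `id`, `smiles` plus generator annotations:
#'   `group` (functional-group tag), `stereo` (`"cis"`, `"trans"` or `NA`)
#'   and `partner` (the id of a stereo drug's isomer twin).
#' @export
generate_drug_library <- function(spec = synth_spec()) {
  with_seed(spec$seed, {
    n <- spec$n_drugs
    n_stereo_pairs <- floor(spec$stereo_fraction * n / 2)
    n_plain <- n - 2L * n_stereo_pairs
    rows <- list()
    seen <- character(0)

    add_row <- function(smiles, group, stereo, partner) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        id = sprintf("D%03d", length(rows) + 1L), smiles = smiles,
        group = group, stereo = stereo, partner = partner)
    }

    # plain drugs: alkyl prefix + backbone + one functional group, unique
    # canonical form; the prefix multiplies the combinatorial space so large
    # libraries stay feasible
    groups <- names(SYNTH_GROUPS)
    prefixes <- c("", "C", "CC", "CCC", "CC(C)", "CCCC")
    gi <- 0L
    attempts <- 0L
    while (n_plain > 0) {
      attempts <- attempts + 1L
      if (attempts > 200L * spec$n_drugs) {
        stop("could not assemble ", spec$n_drugs,
             " unique drugs from the template space", call. = FALSE)
      }
      bb <- SYNTH_BACKBONES[sample.int(length(SYNTH_BACKBONES), 1L)]
      pre <- prefixes[sample.int(length(prefixes), 1L)]
      gi <- gi + 1L
      grp <- groups[(gi - 1L) %% length(groups) + 1L]
      smi <- paste0(pre, bb, SYNTH_GROUPS[[grp]])
      key <- try(canonical_smiles(smi), silent = TRUE)
      if (inherits(key, "try-error") || key %in% seen) next
      seen <- c(seen, key)
      add_row(smi, grp, NA_character_, NA_character_)
      n_plain <- n_plain - 1L
    }

    # stereo pairs: identical constitution, opposite double-bond geometry
    k <- 0L
    attempts <- 0L
    while (k < n_stereo_pairs) {
      attempts <- attempts + 1L
      if (attempts > 200L * max(n_stereo_pairs, 1L)) {
        stop("could not assemble ", n_stereo_pairs,
             " unique stereo pairs from the template space", call. = FALSE)
      }
      l <- SYNTH_STEREO_LEFT[sample.int(length(SYNTH_STEREO_LEFT), 1L)]
      r <- SYNTH_STEREO_RIGHT[sample.int(length(SYNTH_STEREO_RIGHT), 1L)]
      cis <- sprintf("%s/C=C\\%s", l, r)
      trans <- sprintf("%s/C=C/%s", l, r)
      keys <- try(c(canonical_smiles(cis), canonical_smiles(trans)), silent = TRUE)
      if (inherits(keys, "try-error") || any(keys %in% seen) ||
          keys[1] == keys[2]) next
      seen <- c(seen, keys)
      id_cis <- sprintf("D%03d", length(rows) + 1L)
      id_trans <- sprintf("D%03d", length(rows) + 2L)
      add_row(cis, "stereo", "cis", id_trans)
      add_row(trans, "stereo", "trans", id_cis)
      k <- k + 1L
    }
    dplyr::bind_rows(rows)
  })
}

#' Generate rule-based interaction labels over a registry
#'
#' Applies the rule book (see the module header), flips each label to a
#' random different type with probability `label_noise`, and omits pairs
#' firing no rule.
#'
#' @param registry Output of [generate_drug_library()] (the annotation
#'   columns are required).
#' @param spec The matching [synth_spec()].
#' @return A triples tibble (`drug_a`, `drug_b`, `type`).
#' @export
generate_ddi_labels <- function(registry, spec = synth_spec()) {
  stopifnot(all(c("group", "stereo") %in% names(registry)))
  with_seed(spec$seed + 1L, {
    ids <- registry$id
    grp <- stats::setNames(registry$group, ids)
    ste <- stats::setNames(registry$stereo, ids)
    pairs <- utils::combn(ids, 2L)
    a <- pairs[1, ]; b <- pairs[2, ]
    type <- rep(NA_integer_, length(a))
    type[grp[a] == "acid" & grp[b] == "acid"] <- 1L
    if (spec$n_types >= 2) {
      type[(grp[a] == "acid" & grp[b] == "amine") |
           (grp[a] == "amine" & grp[b] == "acid")] <- 2L
    }
    if (spec$n_types >= 3) {
      cis_a <- !is.na(ste[a]) & ste[a] == "cis"
      cis_b <- !is.na(ste[b]) & ste[b] == "cis"
      type[(cis_a & grp[b] == "hydroxyl") | (cis_b & grp[a] == "hydroxyl")] <- 3L
    }
    keep <- !is.na(type)
    if (!any(keep)) {
      stop("registry contains no rule-eligible pair", call. = FALSE)
    }
    out <- tibble::tibble(drug_a = a[keep], drug_b = b[keep], type = type[keep])
    if (is.finite(spec$max_triples) && nrow(out) > spec$max_triples) {
      # stratified down-sampling keeps every type represented
      out <- dplyr::slice_sample(
        dplyr::group_by(out, .data$type),
        prop = min(1, spec$max_triples / nrow(out)))
      out <- dplyr::ungroup(out)
    }
    if (spec$label_noise > 0 && spec$n_types > 1) {
      flip <- stats::runif(nrow(out)) < spec$label_noise
      newt <- vapply(out$type[flip], function(tt) {
        sample(setdiff(seq_len(spec$n_types), tt), 1L)
      }, integer(1))
      out$type[flip] <- newt
    }
    out
  })
}

#' Stereo-aware hard negatives for evaluation
#'
#' For triples whose stereo rule fired (a cis drug paired with a hydroxyl
#' carrier), the negative swaps the cis member for its trans twin - a
#' counterfactual with an identical 2D graph. All other triples are
#' corrupted uniformly. This evaluation protocol exposes the negatives that
#' only the 3D pathway can reject.
#'
#' @param triples Positive triples over `registry`.
#' @param registry A registry with `stereo` and `partner` annotations.
#' @param seed Seed for the uniform corruptions.
#' @return A negatives tibble aligned with `triples`.
#' @export
stereo_hard_negatives <- function(triples, registry, seed = 7L) {
  stopifnot(all(c("stereo", "partner") %in% names(registry)))
  ste <- stats::setNames(registry$stereo, registry$id)
  par <- stats::setNames(registry$partner, registry$id)
  out <- triples
  cis_a <- !is.na(ste[triples$drug_a]) & ste[triples$drug_a] == "cis"
  cis_b <- !is.na(ste[triples$drug_b]) & ste[triples$drug_b] == "cis"
  swap <- cis_a | cis_b
  out$drug_a[cis_a] <- par[triples$drug_a[cis_a]]
  out$drug_b[cis_b & !cis_a] <- par[triples$drug_b[cis_b & !cis_a]]
  if (any(!swap)) {
    unif <- with_seed(seed, sample_negatives(triples[!swap, , drop = FALSE],
                                             registry$id, known = triples))
    out$drug_a[!swap] <- unif$drug_a
    out$drug_b[!swap] <- unif$drug_b
  }
  out$collision <- FALSE
  out
}

#' Build the stereochemistry probe task
#'
#' A balanced binary task: each example pairs a hydroxyl-bearing probe drug
#' with either the cis (label 1) or the trans (label 0) member of an E/Z
#' isomer pair. The two classes have identical 2D graph multisets by
#' construction, so any model without 3D information is forced to chance;
#' the conformer geometries differ, so the 3D pathway can separate them.
#'
#' @param n_pairs Total number of examples (even; half per class).
#' @param seed Generator seed.
#' @return List with `registry`, `triples` (the cis positives, type 1) and
#'   `negatives` (the matched trans counterfactuals, same probes).
#' @export
make_stereo_task <- function(n_pairs = 200L, seed = 1L) {
  stopifnot(n_pairs >= 2, n_pairs %% 2 == 0)
  half <- n_pairs %/% 2L
  with_seed(seed, {
    # isomer pairs
    combos <- expand.grid(l = SYNTH_STEREO_LEFT, r = SYNTH_STEREO_RIGHT,
                          stringsAsFactors = FALSE)
    combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
    rows <- list()
    seen <- character(0)
    for (i in seq_len(nrow(combos))) {
      cis <- sprintf("%s/C=C\\%s", combos$l[i], combos$r[i])
      trans <- sprintf("%s/C=C/%s", combos$l[i], combos$r[i])
      keys <- try(c(canonical_smiles(cis), canonical_smiles(trans)), silent = TRUE)
      if (inherits(keys, "try-error") || any(keys %in% seen) ||
          keys[1] == keys[2]) next
      seen <- c(seen, keys)
      k <- length(rows) / 2L + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("S%03dc", k), smiles = cis, group = "stereo",
        stereo = "cis", partner = sprintf("S%03dt", k))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("S%03dt", k), smiles = trans, group = "stereo",
        stereo = "trans", partner = sprintf("S%03dc", k))
    }
    iso <- dplyr::bind_rows(rows)
    n_iso_pairs <- nrow(iso) / 2L

    # hydroxyl probes
    probes <- list()
    seen_p <- character(0)
    for (bb in SYNTH_BACKBONES) {
      smi <- paste0(bb, SYNTH_GROUPS[["hydroxyl"]])
      key <- try(canonical_smiles(smi), silent = TRUE)
      if (inherits(key, "try-error") || key %in% seen_p) next
      seen_p <- c(seen_p, key)
      probes[[length(probes) + 1L]] <- tibble::tibble(
        id = sprintf("P%03d", length(probes) + 1L), smiles = smi,
        group = "hydroxyl", stereo = NA_character_, partner = NA_character_)
    }
    probes <- dplyr::bind_rows(probes)

    # examples: probe x isomer pair, cycling through both pools
    pi_ <- rep(seq_len(nrow(probes)), length.out = half)
    ii <- rep(seq_len(n_iso_pairs), length.out = half)
    cis_ids <- iso$id[iso$stereo == "cis"][ii]
    trans_ids <- iso$id[iso$stereo == "trans"][ii]
    probe_ids <- probes$id[pi_]
    dup <- duplicated(paste(probe_ids, cis_ids))
    if (any(dup)) {
      # rotate probes for duplicated combinations
      probe_ids[dup] <- probes$id[(pi_[dup] + seq_len(sum(dup))) %% nrow(probes) + 1L]
    }
    list(
      registry = dplyr::bind_rows(iso, probes),
      triples = tibble::tibble(drug_a = probe_ids, drug_b = cis_ids, type = 1L),
      negatives = tibble::tibble(drug_a = probe_ids, drug_b = trans_ids, type = 1L)
    )
  })
}
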