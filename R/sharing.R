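#' Species sets per habitat at one sampling time
#'
#' For each habitat, the union of species observed (count > 0) across that
#' habitat's samples at the given sampling time.
#'
#' @param table an \code{abundance_table}
#' @param meta a \code{sample_meta}
#' @param time sampling-time label present in the metadata
#' @return object of class \code{habitat_species_sets}: a named list of
#'   character vectors (one per habitat) with attribute \code{time}
#' @export
habitat_species_sets <- function(table, meta, time) {
  m <- meta_for(table, meta)
  if (!time %in% m$time) stop("unknown sampling time: ", time, call. = FALSE)
  keep <- m$time == time
  habs <- sort(unique(m$habitat[keep]))
  sets <- lapply(habs, function(h) {
    rows <- keep & m$habitat == h
    sub <- unclass(table)[rows, , drop = FALSE]
    colnames(sub)[colSums(sub) > 0]
  })
  names(sets) <- habs
  structure(sets, time = time, class = "habitat_species_sets")
}

#' Classify species as common, endemic, or shifting
#'
#' Per sampling time, a species observed in all H habitats is common, in
#' exactly one habitat endemic, and in an intermediate number (2..H-1)
#' shifting. The three categories partition the species observed at that
#' time.
#'
#' @param sets a \code{habitat_species_sets} (needs >= 2 habitats)
#' @return object of class \code{sharing_classification}: list with
#'   \code{time}, \code{n_habitats}, \code{habitats}, \code{category} (named
#'   character vector over the time's species union) and \code{habitat_combo}
#'   (named list: species -> sorted habitat vector)
#' @export
classify_species <- function(sets) {
  if (length(sets) < 2L) {
    stop("classification requires >= 2 habitats (endemism undefined)",
         call. = FALSE)
  }
  H <- length(sets)
  habs <- names(sets)
  species <- sort(unique(unlist(sets, use.names = FALSE)), method = "radix")
  combo <- lapply(species, function(s) habs[vapply(sets, function(x) s %in% x, logical(1))])
  names(combo) <- species
  k <- lengths(combo)
  category <- ifelse(k == H, "common", ifelse(k == 1L, "endemic", "shifting"))
  names(category) <- species
  stopifnot(all(category %in% c("common", "endemic", "shifting")))
  structure(list(time = attr(sets, "time"), n_habitats = H, habitats = habs,
                 category = category, habitat_combo = combo),
            class = "sharing_classification")
}

#' Count k-habitat users by habitat combination
#'
#' Shifting species are subdivided by how many habitats they occupy:
#' two-habitat users, three-habitat users, and so on up to H-1.
#'
#' @param cls a \code{sharing_classification}
#' @param k combination size, 2 <= k <= H-1
#' @return named integer vector: counts keyed by habitat combination
#'   (habitats joined with "+", sorted); combinations with no species are
#'   included as zeros
#' @export
k_habitat_users <- function(cls, k) {
  H <- cls$n_habitats
  if (k < 2L || k > H - 1L) {
    stop(sprintf("k must be in [2, %d], got %s", H - 1L, k), call. = FALSE)
  }
  combos <- utils::combn(cls$habitats, k, paste, collapse = "+")
  counts <- setNames(integer(length(combos)), combos)
  shifting <- names(cls$category)[cls$category == "shifting"]
  for (s in shifting) {
    cb <- cls$habitat_combo[[s]]
    if (length(cb) == k) {
      key <- paste(sort(cb), collapse = "+")
      counts[key] <- counts[key] + 1L
    }
  }
  counts
}

#' Jaccard similarity of two species sets
#'
#' J = S_ab / (S_a + S_b - S_ab), the shared richness over the union richness.
#'
#' @param setA,setB character vectors of species ids (union must be nonempty)
#' @return similarity in [0, 1]
#' @export
jaccard_index <- function(setA, setB) {
  setA <- unique(setA)
  setB <- unique(setB)
  u <- length(union(setA, setB))
  if (u == 0L) stop("Jaccard undefined: both sets empty", call. = FALSE)
  length(intersect(setA, setB)) / u
}

#' Shared species and Jaccard similarity for every habitat pair
#'
#' @param sets a \code{habitat_species_sets} (>= 2 habitats)
#' @return data.frame with one row per unordered habitat pair: richness of
#'   each habitat, shared count, and Jaccard percentage rounded half-up to one
#'   decimal
#' @export
pairwise_sharing <- function(sets) {
  if (length(sets) < 2L) stop("need >= 2 habitats", call. = FALSE)
  habs <- names(sets)
  pairs <- utils::combn(habs, 2)
  out <- data.frame(
    habitat_a = pairs[1, ], habitat_b = pairs[2, ],
    richness_a = NA_integer_, richness_b = NA_integer_,
    shared = NA_integer_, jaccard_pct = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(ncol(pairs))) {
    a <- sets[[pairs[1, i]]]
    b <- sets[[pairs[2, i]]]
    out$richness_a[i] <- length(a)
    out$richness_b[i] <- length(b)
    out$shared[i] <- length(intersect(a, b))
    out$jaccard_pct[i] <- round_half_up(100 * jaccard_index(a, b), 1)
  }
  out
}

#' Sharing summary table (counts and percentages per habitat and overall)
#'
#' Mirrors the survey-style summary: for each habitat, how many of its species
#' are common / endemic / shifting with percentages relative to the habitat's
#' richness; the ALL column counts each category over the time's species union
#' with percentages relative to that union; habitat totals carry percentages
#' relative to the union. Partition identities (common + endemic + shifting =
#' richness, per habitat and overall) are asserted on every run.
#'
#' @param sets a \code{habitat_species_sets}
#' @param cls optional pre-computed \code{sharing_classification}
#' @return data.frame with columns habitat, category, count, pct (half-up, one
#'   decimal); habitat "ALL" rows summarize the union, category "total" rows
#'   the richness
#' @export
sharing_summary <- function(sets, cls = classify_species(sets)) {
  habs <- cls$habitats
  union_n <- length(cls$category)
  rows <- list()
  for (h in habs) {
    in_h <- vapply(cls$habitat_combo, function(cb) h %in% cb, logical(1))
    rich <- sum(in_h)
    for (cat in c("common", "endemic", "shifting")) {
      n <- sum(in_h & cls$category == cat)
      rows[[length(rows) + 1L]] <- data.frame(
        habitat = h, category = cat, count = n,
        pct = round_half_up(100 * n / rich, 1), stringsAsFactors = FALSE)
    }
    stopifnot(sum(vapply(rows[(length(rows) - 2):length(rows)],
                         function(r) r$count, numeric(1))) == rich)
    rows[[length(rows) + 1L]] <- data.frame(
      habitat = h, category = "total", count = rich,
      pct = round_half_up(100 * rich / union_n, 1), stringsAsFactors = FALSE)
  }
  cat_tot <- 0L
  for (cat in c("common", "endemic", "shifting")) {
    n <- sum(cls$category == cat)
    cat_tot <- cat_tot + n
    rows[[length(rows) + 1L]] <- data.frame(
      habitat = "ALL", category = cat, count = n,
      pct = round_half_up(100 * n / union_n, 1), stringsAsFactors = FALSE)
  }
  stopifnot(cat_tot == union_n)
  rows[[length(rows) + 1L]] <- data.frame(
    habitat = "ALL", category = "total", count = union_n, pct = 100,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "time") <- cls$time
  out
}

#' Cross-time roll-ups of species commonality
#'
#' Two views of commonality across sampling times, reported side by side:
#' species classified as common at every sampling time ("consistent"), and
#' species common in at least one time ("any_time"). Also reports the total
#' number of distinct species over all times, so overall proportions can be
#' formed either way.
#'
#' @param cls_list list of \code{sharing_classification}, one per time
#' @return list with \code{common_consistent}, \code{common_any_time}
#'   (character vectors), \code{n_species_total}, and per-time species unions
#' @export
cross_time_commonality <- function(cls_list) {
  commons <- lapply(cls_list, function(cl) names(cl$category)[cl$category == "common"])
  unions <- lapply(cls_list, function(cl) names(cl$category))
  list(
    common_consistent = sort(Reduce(intersect, commons)),
    common_any_time = sort(Reduce(union, commons)),
    n_species_total = length(Reduce(union, unions)),
    species_by_time = unions
  )
}
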