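resolve_cluster_frames <- function(fp, cluster) {
  all_frames <- as.integer(rownames(fp$matrix))
  frames <- if (inherits(cluster, "contact_clusters")) {
    cluster_frames(cluster, dominant_cluster(cluster)$cluster)
  } else {
    as.integer(cluster)
  }
  if (!length(frames)) abort("cluster contains no frames.")
  if (!all(frames %in% all_frames)) {
    abort("cluster frames are not a subset of the fingerprint frames.")
  }
  frames
}

#' Contact-persistence network of a structural state
#'
#' One edge per canonical (chain-pair slot, residue pair) contact whose
#' persistence -- the fraction of the cluster's frames containing it -- is at
#' least `display_threshold`. Nodes are residues labeled with their
#' one-letter amino-acid code; chain roles are the canonical slot labels.
#'
#' @param fp A [contact_fingerprints()] object.
#' @param cluster A [cluster_states()] result (its dominant cluster is used)
#'   or an integer vector of frame ids.
#' @param display_threshold Minimum persistence for an edge, in (0, 1].
#' @return Edge tibble of class `contact_network`: `chain_a`, `res_a`,
#'   `aa_a`, `chain_b`, `res_b`, `aa_b`, `persistence`.
#' @export
build_network <- function(fp, cluster, display_threshold = 0.25) {
  stopifnot(inherits(fp, "contact_fingerprints"))
  if (display_threshold <= 0 || display_threshold > 1) {
    abort("display_threshold must lie in (0, 1].")
  }
  frames <- resolve_cluster_frames(fp, cluster)
  pers <- contact_probability(fp, frames)
  seq1 <- zf0_sequence()
  aa_of <- function(r) {
    out <- unname(seq1[as.character(r)])
    out[is.na(out)] <- "X"
    out
  }
  edges <- pers |>
    filter(.data$probability >= display_threshold) |>
    mutate(
      chain_a = LETTERS[.data$slot_a], chain_b = LETTERS[.data$slot_b],
      aa_a = aa_of(.data$res_a), aa_b = aa_of(.data$res_b)
    ) |>
    select("chain_a", "res_a", "aa_a", "chain_b", "res_b", "aa_b",
           persistence = "probability") |>
    arrange(.data$chain_a, .data$chain_b, .data$res_a, .data$res_b)
  attr(edges, "display_threshold") <- display_threshold
  attr(edges, "frames") <- frames
  class(edges) <- c("contact_network", class(edges))
  edges
}

#' @describeIn build_network Residue-level network plot, faceted by chain
#'   pair; line alpha encodes persistence.
#' @param object A `contact_network`.
#' @param ... Unused.
#' @method autoplot contact_network
#' @export
autoplot.contact_network <- function(object, ...) {
  df <- mutate(as_tibble(object),
               pair = paste(.data$chain_a, .data$chain_b, sep = "-"),
               from = paste0(.data$aa_a, .data$res_a),
               to = paste0(.data$aa_b, .data$res_b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$res_a, y = .data$res_b,
                                   alpha = .data$persistence)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "residue (first chain)", y = "residue (second chain)",
                  alpha = "persistence") +
    ggplot2::theme_minimal()
}

# unordered "a-b" keys for pair-set comparisons
norm_pairs <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")

jaccard <- function(x, y) {
  if (!length(x) && !length(y)) return(1)
  length(intersect(x, y)) / length(union(x, y))
}

# similarity of two oriented pair sets, allowing a chain-role swap of one
swap_jaccard <- function(pa, pb) {
  k1 <- paste(pa$res_a, pa$res_b, sep = "-")
  k2 <- paste(pb$res_a, pb$res_b, sep = "-")
  k2s <- paste(pb$res_b, pb$res_a, sep = "-")
  max(jaccard(k1, k2), jaccard(k1, k2s))
}

#' Classify interfaces of a structural state
#'
#' Groups the persistent contacts (persistence >= `membership_threshold`
#' within the cluster) of each unordered chain pair, then merges chain pairs
#' whose residue-pair sets are identical up to swapping the two chains'
#' roles (Jaccard similarity >= `merge_threshold`) into one interface class.
#' A class's multiplicity is the number of chain pairs carrying it. Classes
#' are ranked by descending total persistence and labeled `IF-1`, `IF-2`,
#' ...; the best-matching published interface (by fraction of its contact
#' list recovered) is reported, never assumed.
#'
#' @inheritParams build_network
#' @param membership_threshold Minimum persistence for a contact to count as
#'   part of an interface (default 0.5).
#' @param merge_threshold Jaccard similarity above which two chain pairs are
#'   the same interface class (default 0.8).
#' @param reference Published interface lists to report matches against
#'   (default [reference_interfaces()]); `NULL` to skip.
#' @return Tibble of class `interface_classes`: one row per class with
#'   `class`, `multiplicity`, `n_pairs`, `mean_persistence`,
#'   `total_persistence`, list-columns `placements` and `pairs`, and (when
#'   `reference` is given) `best_match` and `match_recall`. Empty (zero-row)
#'   when no contact passes the threshold: a fully dissociated state.
#' @export
classify_interfaces <- function(fp, cluster, membership_threshold = 0.5,
                                merge_threshold = 0.8,
                                reference = reference_interfaces()) {
  stopifnot(inherits(fp, "contact_fingerprints"))
  frames <- resolve_cluster_frames(fp, cluster)
  pers <- contact_probability(fp, frames)
  pers <- filter(pers, .data$probability >= membership_threshold)
  empty <- tibble(
    class = character(), multiplicity = integer(), n_pairs = integer(),
    mean_persistence = double(), total_persistence = double(),
    placements = list(), pairs = list()
  )
  if (!nrow(pers)) {
    class(empty) <- c("interface_classes", class(empty))
    return(empty)
  }
  slots <- pers |>
    tidyr::nest(pairs = c("res_a", "res_b", "probability")) |>
    arrange(.data$slot_a, .data$slot_b)
  ns <- nrow(slots)
  comp <- seq_len(ns) # union-find over chain-pair slots
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (ns > 1) {
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
      if (swap_jaccard(slots$pairs[[i]], slots$pairs[[j]]) >= merge_threshold) {
        ri <- find(i); rj <- find(j)
        comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(ns), find, integer(1))
  out <- purrr::map_dfr(unique(roots), function(r) {
    members <- which(roots == r)
    # representative slot: largest summed persistence
    tp <- vapply(members, function(i) sum(slots$pairs[[i]]$probability), numeric(1))
    rep_i <- members[which.max(tp)]
    rep_pairs <- slots$pairs[[rep_i]]
    tibble(
      multiplicity = length(members),
      n_pairs = nrow(rep_pairs),
      mean_persistence = mean(unlist(lapply(members, function(i)
        slots$pairs[[i]]$probability))),
      total_persistence = sum(tp),
      placements = list(paste(LETTERS[slots$slot_a[members]],
                              LETTERS[slots$slot_b[members]], sep = "-")),
      pairs = list(rename(rep_pairs, persistence = "probability"))
    )
  })
  out <- arrange(out, dplyr::desc(.data$total_persistence))
  out <- mutate(out, class = paste0("IF-", dplyr::row_number()), .before = 1)
  if (!is.null(reference)) {
    ref_sets <- split(norm_pairs(reference$res_a, reference$res_b),
                      reference$interface)
    matches <- purrr::map_dfr(out$pairs, function(p) {
      keys <- unique(norm_pairs(p$res_a, p$res_b))
      recall <- vapply(ref_sets, function(rs)
        length(intersect(unique(rs), keys)) / length(unique(rs)), numeric(1))
      tibble(best_match = names(ref_sets)[which.max(recall)],
             match_recall = max(recall))
    })
    out <- dplyr::bind_cols(out, matches)
  }
  class(out) <- c("interface_classes", class(out))
  out
}

#' Per-frame assembly order of the complex
#'
#' Chains are linked in a frame when at least `min_edges_per_link` residue
#' contacts join them; the assembly order of the frame is the size of the
#' largest connected chain component. The modal order over frames (ties
#' resolve to the larger order) summarizes the ensemble.
#'
#' @param contacts Output of [extract_contacts()].
#' @param min_edges_per_link Minimum residue contacts per chain-chain link
#'   (default 3, robust against single spurious contacts).
#' @return Object of class `assembly_report`: list with `per_frame` (tibble
#'   `frame`, `largest_component`), `histogram` (tibble `order`,
#'   `n_frames`), `modal_order` and `n_chains`.
#' @export
infer_assembly_order <- function(contacts, min_edges_per_link = 3) {
  chains <- attr(contacts, "chains")
  frames <- attr(contacts, "frames")
  if (is.null(chains) || is.null(frames)) {
    abort("`contacts` must come from extract_contacts().")
  }
  nc <- length(chains)
  links <- contacts |>
    count(.data$frame, .data$chain_a, .data$chain_b) |>
    filter(.data$n >= min_edges_per_link)
  sizes <- setNames(rep(1L, length(frames)), as.character(frames))
  if (nrow(links)) {
    per <- split(links, links$frame)
    for (nm in names(per)) {
      comp <- seq_len(nc)
      find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
      la <- match(per[[nm]]$chain_a, chains)
      lb <- match(per[[nm]]$chain_b, chains)
      for (e in seq_along(la)) {
        ra <- find(la[e]); rb <- find(lb[e])
        comp[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(nc), find, integer(1))
      sizes[nm] <- max(table(roots))
    }
  }
  per_frame <- tibble(frame = frames, largest_component = as.integer(sizes))
  hist <- count(per_frame, order = .data$largest_component, name = "n_frames")
  modal <- max(hist$order[hist$n_frames == max(hist$n_frames)])
  structure(
    list(per_frame = per_frame, histogram = hist,
         modal_order = as.integer(modal), n_chains = nc),
    class = "assembly_report"
  )
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf("<assembly_report> modal assembly order %d of %d chains\n",
              x$modal_order, x$n_chains))
  print(x$histogram)
  invisible(x)
}

#' @describeIn infer_assembly_order Per-frame largest-component sizes.
#' @param x An `assembly_report`.
#' @param ... Unused.
#' @method tidy assembly_report
#' @export
tidy.assembly_report <- function(x, ...) x$per_frame

#' @describeIn infer_assembly_order One-row summary.
#' @method glance assembly_report
#' @export
glance.assembly_report <- function(x, ...) {
  tibble(modal_order = x$modal_order, n_chains = x$n_chains,
         n_frames = sum(x$histogram$n_frames))
}

#' @describeIn infer_assembly_order Histogram of assembly orders.
#' @param object An `assembly_report`.
#' @method autoplot assembly_report
#' @export
autoplot.assembly_report <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(factor(.data$order), .data$n_frames)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "largest connected chain component",
                  y = "frames") +
    ggplot2::theme_minimal()
}
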