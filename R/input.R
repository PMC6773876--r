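# Input processing: significance filtering and reconciliation of input gene
# symbols with the interaction network.

#' Filter a DEG table by adjusted p value
#'
#' Keeps rows with `p <= threshold` (the boundary is inclusive), preserving
#' input order.
#'
#' @param deg a [deg_table()].
#' @param threshold significance threshold in `(0, 1]` (default 0.05).
#' @return The filtered `deg_table`; warns if no row survives.
#' @export
filter_significant <- function(deg, threshold = 0.05) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop_input("threshold must be in (0, 1]")
  out <- deg[deg$p <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no genes pass the significance threshold ", threshold,
            call. = FALSE)
  out
}

#' Map significant genes onto the interaction network
#'
#' Symbols already present in the network are kept as-is. Symbols absent
#' from the network whose alias-map image is a network node are renamed to
#' that image; the remainder are dropped with reason `"not-in-PIN"`. If a
#' rename collides with an already-kept symbol, the lower-p record wins
#' (consistent with the multi-probe rule of [read_deg_table()]).
#'
#' @param deg a significance-filtered [deg_table()].
#' @param pin an [interaction_network()].
#' @param aliases optional named character vector (`alias -> canonical`,
#'   see [read_alias_map()]), or `NULL` to skip conversion.
#' @return A `processed_input`: list with `deg` (the mapped `deg_table`,
#'   every gene a network node), `genes` (its symbols), `p` and `change`
#'   (named vectors; `change` is `NULL` when absent) and `dropped`
#'   (data.frame of gene + reason, `"not-in-PIN"` or `"alias-collision"`),
#'   so kept plus dropped rows always account for every input row.
#' @export
map_to_pin <- function(deg, pin, aliases = NULL) {
  stopifnot(inherits(pin, "interaction_network"))
  gene <- deg$gene
  in_pin <- gene %in% pin$nodes
  renamed <- rep(NA_character_, length(gene))
  if (!is.null(aliases)) {
    cand <- !in_pin & gene %in% names(aliases)
    img <- unname(aliases[gene[cand]])
    ok <- img %in% pin$nodes
    renamed[which(cand)[ok]] <- img[ok]
  }
  keep <- in_pin | !is.na(renamed)
  eff <- gene
  eff[!is.na(renamed)] <- renamed[!is.na(renamed)]
  mapped <- deg[keep, , drop = FALSE]
  mapped$gene <- eff[keep]
  # rename collisions: minimum p wins, first occurrence breaks ties; the
  # losing records are reported as dropped so that kept + dropped always
  # partitions the input
  o <- order(mapped$p)
  mapped <- mapped[o, , drop = FALSE]
  dup <- duplicated(mapped$gene)
  collided <- gene[keep][o][dup]
  mapped <- mapped[!dup, , drop = FALSE]
  mapped <- mapped[order(match(mapped$gene, eff)), , drop = FALSE]
  rownames(mapped) <- NULL
  dropped <- rbind(
    data.frame(gene = gene[!keep],
               reason = rep("not-in-PIN", sum(!keep)),
               stringsAsFactors = FALSE),
    data.frame(gene = collided,
               reason = rep("alias-collision", length(collided)),
               stringsAsFactors = FALSE))
  structure(list(
    deg = mapped,
    genes = mapped$gene,
    p = stats::setNames(mapped$p, mapped$gene),
    change = if ("change" %in% names(mapped))
      stats::setNames(mapped$change, mapped$gene) else NULL,
    dropped = dropped
  ), class = "processed_input")
}

#' @export
print.processed_input <- function(x, ...) {
  cat("processed_input:", length(x$genes), "significant genes in PIN;",
      nrow(x$dropped), "dropped (not-in-PIN)\n")
  invisible(x)
}

#' Process a DEG table for active subnetwork search
#'
#' Convenience wrapper: [filter_significant()] then [map_to_pin()].
#'
#' @inheritParams filter_significant
#' @inheritParams map_to_pin
#' @return A `processed_input` (see [map_to_pin()]); its `dropped` table
#'   records both `"not-significant"` and `"not-in-PIN"` genes.
#' @export
process_input <- function(deg, pin, threshold = 0.05, aliases = NULL) {
  sig <- filter_significant(deg, threshold)
  out <- map_to_pin(sig, pin, aliases)
  not_sig <- setdiff(deg$gene, sig$gene)
  if (length(not_sig) > 0L)
    out$dropped <- rbind(
      data.frame(gene = not_sig, reason = "not-significant",
                 stringsAsFactors = FALSE),
      out$dropped)
  out
}
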