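#' Simulation configuration for a synthetic paralog family
#'
#' Bundles the parameters of the gene-family simulator. Defaults describe a
#' recently expanded family: 8 paralogs diverged from a 3 kb ancestor by
#' point substitutions at 5% per bp and short indels at 0.5% per bp, with
#' geometric indel lengths (mean 2 bp).
#'
#' @param seed integer master seed; every generator derives its own stream
#'   from it, so identical seeds give byte-identical families.
#' @param n_paralogs number of paralogous loci (the emulated families have
#'   8-16 members).
#' @param ancestor_length length of the common ancestor, bp.
#' @param substitution_rate per-bp substitution probability per paralog.
#' @param indel_rate per-bp probability of starting an indel.
#' @param indel_geom_p geometric parameter for indel length (length =
#'   1 + Geom(p)).
#' @param depth expected number of Tn5 insertion events per locus in
#'   [simulate_insertions()].
#' @param hotspot_multiplier default fold-enrichment for planted hotspots.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_paralogs = 8L, ancestor_length = 3000L,
                       substitution_rate = 0.05, indel_rate = 0.005,
                       indel_geom_p = 0.5, depth = 2000,
                       hotspot_multiplier = 3) {
  if (!is.numeric(ancestor_length) || ancestor_length < 1)
    stop("invalid config: ancestor_length must be >= 1")
  if (n_paralogs < 1) stop("invalid config: n_paralogs must be >= 1")
  rates <- c(substitution_rate, indel_rate, indel_geom_p)
  if (any(rates < 0) || any(rates[1:2] > 1) || indel_geom_p > 1)
    stop("invalid config: rates must lie in [0, 1]")
  if (depth < 0 || hotspot_multiplier < 0)
    stop("invalid config: depth and hotspot_multiplier must be >= 0")
  structure(list(seed = as.integer(seed), n_paralogs = as.integer(n_paralogs),
                 ancestor_length = as.integer(ancestor_length),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate, indel_geom_p = indel_geom_p,
                 depth = depth, hotspot_multiplier = hotspot_multiplier),
            class = "sim_config")
}

#' Generate a synthetic paralogous gene family
#'
#' Simulates the duplication of a random ancestral locus into `n_paralogs`
#' copies, each diverged by independent substitutions (uniform over the three
#' alternative bases) and short geometric-length indels. The true multiple
#' alignment is built constructively from the mutation log -- never
#' re-estimated with an aligner -- so downstream consensus and projection
#' analyses can be tested against exact truth.
#'
#' @param config a [sim_config()].
#' @return An object of class `"paralog_family"` with components:
#'   `ancestor` (sequence), `paralogs` (named character vector),
#'   `msa` (named gapped sequences: ancestor row plus one row per paralog),
#'   `mutation_log` (data frame: paralog, position, kind, payload),
#'   `elements` (planted elements; empty initially), and `config`.
#' @examples
#' fam <- generate_paralog_family(sim_config(seed = 1, n_paralogs = 4,
#'                                           ancestor_length = 300))
#' nchar(fam$ancestor)
#' @export
generate_paralog_family <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  L <- config$ancestor_length
  with_stream_seed(config$seed, "family", {
    ancestor <- random_dna(L)
    anc_bases <- strsplit(ancestor, "")[[1]]
    names <- sprintf("P%02d", seq_len(config$n_paralogs))
    muts <- lapply(names, function(nm) {
      sub_pos <- which(runif(L) < config$substitution_rate)
      sub_base <- if (length(sub_pos)) mutate_bases(anc_bases[sub_pos], 1)
                  else character(0)
      ind_pos <- which(runif(L) < config$indel_rate)
      del <- integer(0)
      ins_pos <- integer(0); ins_seq <- character(0)
      for (p in ind_pos) {
        len <- 1L + rgeom(1L, config$indel_geom_p)
        if (runif(1) < 0.5) {
          span <- p:min(p + len - 1L, L)
          if (!any(span %in% del)) del <- c(del, span)
        } else {
          ins_pos <- c(ins_pos, p)
          ins_seq <- c(ins_seq, random_dna(len))
        }
      }
      list(sub = data.frame(pos = sub_pos, base = sub_base,
                            stringsAsFactors = FALSE),
           del = sort(del),
           ins = data.frame(pos = ins_pos, seq = ins_seq,
                            stringsAsFactors = FALSE))
    })
    names(muts) <- names
    fam <- structure(list(ancestor = ancestor, mutations = muts,
                          elements = list(), config = config),
                     class = "paralog_family")
    rebuild_family(fam)
  })
}

# Recompute every derived field (paralog sequences, true MSA, mutation log)
# from ancestor + per-paralog mutation sets.
rebuild_family <- function(fam) {
  anc_bases <- strsplit(fam$ancestor, "")[[1]]
  L <- length(anc_bases)
  nms <- names(fam$mutations)

  # insertion width needed after each ancestor position (0 = before start)
  ins_w <- integer(L + 1L)
  for (m in fam$mutations) {
    if (nrow(m$ins)) {
      w <- nchar(m$ins$seq)
      idx <- m$ins$pos + 1L
      ins_w[idx] <- pmax(ins_w[idx], w)
    }
  }
  n_col <- L + sum(ins_w)
  # MSA column of ancestor position i (1-based)
  col_of <- seq_len(L) + cumsum(ins_w)[seq_len(L)]
  # first column of the insertion block after ancestor position i (0..L)
  ins_col_start <- c(0L, col_of) + 1L

  build_row <- function(m) {
    row <- rep("-", n_col)
    bases <- anc_bases
    if (nrow(m$sub)) bases[m$sub$pos] <- m$sub$base
    keep <- setdiff(seq_len(L), m$del)
    row[col_of[keep]] <- bases[keep]
    if (nrow(m$ins)) {
      for (k in seq_len(nrow(m$ins))) {
        s <- strsplit(m$ins$seq[k], "")[[1]]
        st <- ins_col_start[m$ins$pos[k] + 1L]
        row[st:(st + length(s) - 1L)] <- s
      }
    }
    row
  }

  msa <- c(list(ancestor = anc_bases_row <- {
    row <- rep("-", n_col); row[col_of] <- anc_bases; row
  }), lapply(fam$mutations, build_row))
  fam$msa <- vapply(msa, paste, character(1), collapse = "")
  names(fam$msa) <- c("ancestor", nms)
  fam$paralogs <- vapply(fam$mutations, function(m) {
    gsub("-", "", paste(build_row(m), collapse = ""), fixed = TRUE)
  }, character(1))
  names(fam$paralogs) <- nms
  fam$anc_column <- col_of

  logs <- lapply(nms, function(nm) {
    m <- fam$mutations[[nm]]
    rbind(
      if (nrow(m$sub)) data.frame(paralog = nm, position = m$sub$pos,
                                  kind = "sub", payload = m$sub$base),
      if (length(m$del)) data.frame(paralog = nm, position = m$del,
                                    kind = "del", payload = "1"),
      if (nrow(m$ins)) data.frame(paralog = nm, position = m$ins$pos,
                                  kind = "ins", payload = m$ins$seq)
    )
  })
  fam$mutation_log <- do.call(rbind, c(logs, list(
    data.frame(paralog = character(0), position = integer(0),
               kind = character(0), payload = character(0)))))
  rownames(fam$mutation_log) <- NULL
  fam
}

#' @export
print.paralog_family <- function(x, ...) {
  cat("Synthetic paralog family:", length(x$paralogs), "paralogs,",
      "ancestor", nchar(x$ancestor), "bp,",
      length(x$elements), "planted element(s)\n")
  invisible(x)
}

#' Reconstruct one paralog from the ancestor and its mutation set
#'
#' Used to check the invariant that every paralog sequence is derivable from
#' `ancestor` plus its mutation log entries.
#'
#' @param fam a `paralog_family`.
#' @param paralog paralog name.
#' @return The reconstructed sequence (character scalar).
#' @export
reconstruct_paralog <- function(fam, paralog) {
  m <- fam$mutations[[paralog]]
  if (is.null(m)) stop("unknown paralog: ", paralog)
  bases <- strsplit(fam$ancestor, "")[[1]]
  if (nrow(m$sub)) bases[m$sub$pos] <- m$sub$base
  L <- length(bases)
  out <- character(0)
  ins_at <- split(m$ins$seq, m$ins$pos)
  if (!is.null(ins_at[["0"]])) out <- c(out, ins_at[["0"]])
  for (i in seq_len(L)) {
    if (!(i %in% m$del)) out <- c(out, bases[i])
    key <- as.character(i)
    if (!is.null(ins_at[[key]])) out <- c(out, ins_at[[key]])
  }
  paste(out, collapse = "")
}

#' Map ancestor positions to coordinates on one paralog
#'
#' @param fam a `paralog_family`.
#' @param paralog paralog name.
#' @return Integer vector over ancestor positions: the 1-based position of
#'   that base on the paralog, or `NA` where the base was deleted.
#' @export
ancestor_to_paralog <- function(fam, paralog) {
  m <- fam$mutations[[paralog]]
  if (is.null(m)) stop("unknown paralog: ", paralog)
  L <- nchar(fam$ancestor)
  ins_len <- integer(L + 1L)
  if (nrow(m$ins)) {
    agg <- tapply(nchar(m$ins$seq), m$ins$pos, sum)
    ins_len[as.integer(names(agg)) + 1L] <- agg
  }
  kept <- !(seq_len(L) %in% m$del)
  # paralog position of ancestor base i = insertions before it + kept bases <= i
  cumsum(kept) + cumsum(ins_len)[seq_len(L)] -> pos
  pos[!kept] <- NA_integer_
  pos
}

#' Plant a conserved regulatory element into a paralog family
#'
#' Overwrites a common homologous interval (in ancestor coordinates) with
#' `element`: carrier paralogs receive it verbatim, non-carriers receive a
#' copy decayed by per-base substitutions at rate `decay`. This emulates a
#' cis-regulatory element conserved in a subset of paralogs and degenerated
#' in the rest. Indels overlapping the interval are removed from every
#' paralog so the element is never split in a carrier and truth coordinate
#' maps stay simple.
#'
#' @param fam a `paralog_family`.
#' @param element element sequence (shorter than the ancestor).
#' @param carriers character vector of paralog names carrying the element
#'   verbatim.
#' @param at 1-based ancestor start position; chosen at random (avoiding
#'   previously planted elements) when `NULL`.
#' @param decay per-base substitution probability applied to non-carrier
#'   copies.
#' @param name element name (default `"E<k>"`).
#' @return The updated `paralog_family`; `fam$elements` gains an entry with
#'   the ancestor interval, carriers and decay rate.
#' @export
plant_conserved_element <- function(fam, element, carriers, at = NULL,
                                    decay = 0.3, name = NULL) {
  len <- nchar(element)
  if (len < 1) stop("planting error: element length 0")
  L <- nchar(fam$ancestor)
  if (len >= L) stop("planting error: element must be shorter than ancestor")
  bad <- setdiff(carriers, names(fam$paralogs))
  if (length(bad)) stop("planting error: unknown carriers: ",
                        paste(bad, collapse = ", "))
  if (is.null(name)) name <- sprintf("E%d", length(fam$elements) + 1L)

  with_stream_seed(fam$config$seed + length(fam$elements), "plant", {
    occupied <- unlist(lapply(fam$elements, function(e) e$start:e$end))
    if (is.null(at)) {
      starts <- setdiff(seq_len(L - len + 1L), unique(unlist(
        lapply(fam$elements, function(e) {
          max(1L, e$start - len + 1L):e$end
        }))))
      if (!length(starts)) stop("planting error: no free interval")
      at <- sample(starts, 1L)
    }
    span <- at:(at + len - 1L)
    if (at < 1 || max(span) > L) stop("planting error: interval out of bounds")
    if (length(intersect(span, occupied)))
      stop("planting error: overlap with a previously planted element")

    elem_bases <- strsplit(toupper(element), "")[[1]]
    anc_bases <- strsplit(fam$ancestor, "")[[1]]
    anc_bases[span] <- elem_bases
    fam$ancestor <- paste(anc_bases, collapse = "")

    for (nm in names(fam$mutations)) {
      m <- fam$mutations[[nm]]
      # the element must not be split by indels in any paralog
      m$del <- setdiff(m$del, span)
      if (nrow(m$ins) && len > 1)
        m$ins <- m$ins[!(m$ins$pos %in% at:(at + len - 2L)), , drop = FALSE]
      m$sub <- m$sub[!(m$sub$pos %in% span), , drop = FALSE]
      if (!(nm %in% carriers) && decay > 0) {
        decayed <- mutate_bases(elem_bases, decay)
        hit <- decayed != elem_bases
        if (any(hit))
          m$sub <- rbind(m$sub, data.frame(pos = span[hit],
                                           base = decayed[hit]))
      }
      fam$mutations[[nm]] <- m
    }
    fam$elements[[name]] <- list(name = name, start = at, end = at + len - 1L,
                                 element = toupper(element),
                                 carriers = carriers, decay = decay)
    rebuild_family(fam)
  })
}

#' MSA column span of a planted element
#'
#' @param fam a `paralog_family`.
#' @param name planted element name.
#' @return Integer vector of MSA column indices covered by the element.
#' @export
element_columns <- function(fam, name) {
  e <- fam$elements[[name]]
  if (is.null(e)) stop("unknown element: ", name)
  fam$anc_column[e$start:e$end]
}

#' Paralog-coordinate intervals of planted elements
#'
#' @param fam a `paralog_family`.
#' @return Data frame with one row per (element, paralog): start/end of the
#'   element footprint in that paralog's own coordinates.
#' @export
element_footprints <- function(fam) {
  out <- lapply(fam$elements, function(e) {
    do.call(rbind, lapply(names(fam$paralogs), function(nm) {
      map <- ancestor_to_paralog(fam, nm)
      data.frame(element = e$name, paralog = nm,
                 start = map[e$start], end = map[e$end])
    }))
  })
  res <- do.call(rbind, c(out, list(data.frame(
    element = character(0), paralog = character(0),
    start = integer(0), end = integer(0)))))
  rownames(res) <- NULL
  res
}
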