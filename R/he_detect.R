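# Homeologous-exchange detection.
#
# In a selfing allotetraploid each subgenome is present at 2 copies, so a
# homeologous exchange shows up as a reciprocal pair of depth anomalies:
# a 0-copy segment on one subgenome whose homeologous projection (via the
# 1:1 gene pairs it contains) is a 4-copy segment on the other. Hi-C trans
# contacts around the breakpoints and discordant read pairs linking the two
# subgenomes corroborate a candidate. Copy states are restricted to
# {0, 2, 4}: heterozygous intermediate states do not arise in a selfer.

#' Assign a copy state to each coverage window
#'
#' The depth ratio r of each window to the genome-wide median depth is
#' thresholded: \code{r < zero_max} gives state 0, \code{two_min <= r <=
#' two_max} state 2, \code{r > four_min} state 4. Ratios falling between
#' the bands are ambiguous and inherit the majority state of their nearest
#' unambiguous neighbours on the same chromosome.
#'
#' @param track a \code{\link{coverage_track}}.
#' @param zero_max,two_min,two_max,four_min ratio thresholds (defaults
#'   0.25, 0.5, 1.5, 1.6).
#' @return data.frame of windows with \code{ratio} and integer
#'   \code{state} (0, 2 or 4).
#' @export
window_copy_states <- function(track, zero_max = 0.25, two_min = 0.5,
                               two_max = 1.5, four_min = 1.6) {
  med <- median(track$depth)
  .assert(med > 0, "genome median depth is zero")
  ratio <- track$depth / med
  state <- rep(NA_integer_, length(ratio))
  state[ratio < zero_max] <- 0L
  state[ratio >= two_min & ratio <= two_max] <- 2L
  state[ratio > four_min] <- 4L
  out <- data.frame(track[, c("chrom", "start", "end")], ratio = ratio,
                    state = state)
  # Ambiguous windows: majority vote of the nearest resolved neighbours.
  for (ch in unique(out$chrom)) {
    idx <- which(out$chrom == ch)
    s <- out$state[idx]
    if (all(is.na(s))) { out$state[idx] <- 2L; next }
    na_pos <- which(is.na(s))
    res_pos <- which(!is.na(s))
    for (i in na_pos) {
      gaps <- abs(res_pos - i)
      nearest <- res_pos[gaps == min(gaps)]
      votes <- s[nearest]
      tab <- table(votes)
      winners <- as.integer(names(tab)[tab == max(tab)])
      s[i] <- if (2L %in% winners) 2L else min(winners)   # tie favours 2
    }
    out$state[idx] <- s
  }
  out
}

#' Collapse window states into maximal same-state segments
#'
#' Maximal runs of identical state per chromosome. Runs shorter than
#' \code{min_run} windows are iteratively absorbed into a flanking run when
#' they are (a) aberrant (state 0 or 4) — the smoothing exists to stop
#' isolated depth blips from becoming copy-number segments — or (b) normal
#' runs sandwiched between two runs of the same aberrant state (a noise gap
#' splitting one event). Short normal runs at other positions, in
#' particular at chromosome ends, are kept: absorbing normal sequence into
#' an adjacent aberrant segment would misplace its breakpoint. Segments
#' tile each chromosome's windowed extent.
#'
#' @param states window state table from \code{\link{window_copy_states}}.
#' @param min_run minimum run length in windows (default 5).
#' @return data.frame of segments: \code{chrom}, \code{start}, \code{end},
#'   \code{state}, \code{n_windows}, \code{mean_ratio}.
#' @export
segment_states <- function(states, min_run = 5) {
  out <- lapply(split(states, states$chrom), function(d) {
    d <- d[order(d$start), ]
    s <- d$state
    repeat {
      r <- rle(s)
      nr <- length(r$lengths)
      if (nr <= 1) break
      short <- which(r$lengths < min_run)
      eligible <- short[vapply(short, function(i) {
        interior_blip <- i > 1 && i < nr && r$values[i - 1] == r$values[i + 1]
        r$values[i] != 2L || interior_blip
      }, logical(1))]
      if (!length(eligible)) break
      i <- eligible[which.min(r$lengths[eligible])]
      left_n <- if (i > 1) r$lengths[i - 1] else -1L
      right_n <- if (i < nr) r$lengths[i + 1] else -1L
      new_val <- if (left_n >= right_n) r$values[i - 1] else r$values[i + 1]
      ends <- cumsum(r$lengths)
      s[(ends[i] - r$lengths[i] + 1):ends[i]] <- new_val
    }
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    data.frame(chrom = d$chrom[1],
               start = d$start[starts], end = d$end[ends],
               state = r$values, n_windows = r$lengths,
               mean_ratio = vapply(seq_along(starts), function(k) {
                 mean(d$ratio[starts[k]:ends[k]])
               }, numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Genes of the annotation contained in a segment (fully inside).
.genes_in_segment <- function(annotation, chrom, start, end) {
  g <- annotation$genes
  g$gene_id[g$chrom == chrom & g$start >= start & g$end <= end]
}

#' Pair reciprocal 0-copy / 4-copy segments into HE candidates
#'
#' A state-0 segment is projected onto the other subgenome through the
#' homeolog partners of the gene pairs it contains; it becomes an HE
#' candidate when the projected gene set and the genes of a state-4 segment
#' on the other subgenome overlap reciprocally (Jaccard index >=
#' \code{min_jaccard}). A 0-copy segment whose homeologous region sits at
#' normal copy number is a plain deletion, not an HE. Segments containing
#' no paired genes cannot be projected and are skipped with a note.
#'
#' @param segments segment table from \code{\link{segment_states}} covering
#'   both subgenomes.
#' @param annotation a \code{\link{genome_annotation}}.
#' @param map homeolog pair table.
#' @param min_jaccard reciprocal-overlap threshold (default 0.5).
#' @return data.frame of candidates: lost and duplicated segment
#'   coordinates, \code{replacing_subgenome} (the subgenome of the
#'   duplicated segment), \code{jaccard}, and breakpoint positions.
#' @export
pair_reciprocal_events <- function(segments, annotation, map,
                                   min_jaccard = 0.5) {
  sg_of <- setNames(annotation$chromosomes$subgenome,
                    annotation$chromosomes$chrom)
  partner <- setNames(annotation$genes$partner, annotation$genes$gene_id)
  seg0 <- segments[segments$state == 0, , drop = FALSE]
  seg4 <- segments[segments$state == 4, , drop = FALSE]
  cand <- list()
  for (i in seq_len(nrow(seg0))) {
    lost_genes <- .genes_in_segment(annotation, seg0$chrom[i],
                                    seg0$start[i], seg0$end[i])
    proj <- partner[lost_genes]
    proj <- proj[!is.na(proj)]
    if (!length(proj)) {
      message("state-0 segment ", seg0$chrom[i], ":", seg0$start[i], "-",
              seg0$end[i], " contains no homeolog pairs; skipped")
      next
    }
    for (j in seq_len(nrow(seg4))) {
      if (sg_of[seg4$chrom[j]] == sg_of[seg0$chrom[i]]) next
      dup_genes <- .genes_in_segment(annotation, seg4$chrom[j],
                                     seg4$start[j], seg4$end[j])
      jac <- length(intersect(proj, dup_genes)) /
        length(union(proj, dup_genes))
      if (is.nan(jac) || jac < min_jaccard) next
      cand[[length(cand) + 1]] <- data.frame(
        lost_chrom = seg0$chrom[i], lost_start = seg0$start[i],
        lost_end = seg0$end[i], lost_subgenome = unname(sg_of[seg0$chrom[i]]),
        dup_chrom = seg4$chrom[j], dup_start = seg4$start[j],
        dup_end = seg4$end[j],
        replacing_subgenome = unname(sg_of[seg4$chrom[j]]),
        jaccard = jac, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(lost_chrom = character(), lost_start = numeric(),
                      lost_end = numeric(), lost_subgenome = character(),
                      dup_chrom = character(), dup_start = numeric(),
                      dup_end = numeric(), replacing_subgenome = character(),
                      jaccard = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, cand)
}

#' Trans-contact enrichment around an HE breakpoint
#'
#' The mean trans contact count over bin pairs within \code{flank} bins of
#' the two breakpoints, divided by the mean trans contact over all bin
#' pairs of that chromosome pair. A uniform trans background gives 1; a
#' planted spike of s gives about s. With a zero background the evidence is
#' undefined and returned as NA (missing evidence).
#'
#' @param contacts a \code{\link{contact_matrix}}.
#' @param chrom1,pos1,chrom2,pos2 the breakpoint pair (bp positions).
#' @param flank bins on each side of each breakpoint (default 2).
#' @return Enrichment ratio (numeric, NA when undefined).
#' @export
contact_enrichment <- function(contacts, chrom1, pos1, chrom2, pos2,
                               flank = 2) {
  b <- contacts$bins
  .assert(all(c(chrom1, chrom2) %in% b$chrom),
          "chromosome absent from contact matrix")
  binsize <- b$end[1] - b$start[1]
  i_all <- which(b$chrom == chrom1)
  j_all <- which(b$chrom == chrom2)
  background <- mean(contacts$counts[i_all, j_all])
  if (!length(i_all) || !length(j_all) || background == 0) return(NA_real_)
  near <- function(idx, pos) {
    idx[abs(b$start[idx] + binsize / 2 - pos) <= (flank + 0.5) * binsize]
  }
  i <- near(i_all, pos1)
  j <- near(j_all, pos2)
  if (!length(i) || !length(j)) return(NA_real_)
  mean(contacts$counts[i, j]) / background
}

#' Count discordant read pairs supporting a breakpoint pair
#'
#' @param pairs data.frame of discordant pairs with columns \code{chromA},
#'   \code{posA}, \code{chromB}, \code{posB}.
#' @param chrom1,pos1,chrom2,pos2 breakpoints.
#' @param window maximum distance (bp) of each end from its breakpoint.
#' @return Integer count (either end order matches).
#' @export
discordant_support <- function(pairs, chrom1, pos1, chrom2, pos2,
                               window = 2000) {
  if (is.null(pairs) || nrow(pairs) == 0) return(0L)
  fwd <- pairs$chromA == chrom1 & abs(pairs$posA - pos1) <= window &
    pairs$chromB == chrom2 & abs(pairs$posB - pos2) <= window
  rev <- pairs$chromA == chrom2 & abs(pairs$posA - pos2) <= window &
    pairs$chromB == chrom1 & abs(pairs$posB - pos1) <= window
  sum(fwd | rev)
}

#' Call homeologous exchanges from candidates and evidence
#'
#' A reciprocal coverage candidate (from
#' \code{\link{pair_reciprocal_events}}) is promoted to an HE call when,
#' given orthogonal evidence, its breakpoint contact enrichment reaches
#' \code{min_contact} or its discordant pair support reaches
#' \code{min_pairs}. When neither a contact matrix nor a discordant pair
#' table is supplied the call rests on coverage reciprocity alone.
#'
#' @param candidates candidate table from
#'   \code{\link{pair_reciprocal_events}}.
#' @param contacts optional \code{\link{contact_matrix}}.
#' @param discordant optional discordant pair table (see
#'   \code{\link{discordant_support}}).
#' @param min_contact minimum contact enrichment (default 2).
#' @param min_pairs minimum discordant pair count (default 3).
#' @param flank,window see \code{\link{contact_enrichment}} and
#'   \code{\link{discordant_support}}.
#' @return The candidate table with evidence columns
#'   (\code{contact_enrichment}, \code{discordant_pairs}) restricted to
#'   retained calls. Breakpoints of the lost segment are its start/end.
#' @export
call_he <- function(candidates, contacts = NULL, discordant = NULL,
                    min_contact = 2.0, min_pairs = 3, flank = 2,
                    window = 2000) {
  if (nrow(candidates) == 0) {
    candidates$contact_enrichment <- numeric(0)
    candidates$discordant_pairs <- integer(0)
    return(candidates)
  }
  ce <- rep(NA_real_, nrow(candidates))
  dp <- rep(NA_integer_, nrow(candidates))
  keep <- rep(TRUE, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cc <- candidates[i, ]
    if (!is.null(contacts)) {
      # Each HE produces two breakpoint pairs (start-start, end-end);
      # take the stronger.
      e1 <- contact_enrichment(contacts, cc$lost_chrom, cc$lost_start,
                               cc$dup_chrom, cc$dup_start, flank)
      e2 <- contact_enrichment(contacts, cc$lost_chrom, cc$lost_end,
                               cc$dup_chrom, cc$dup_end, flank)
      ce[i] <- max(e1, e2, na.rm = !all(is.na(c(e1, e2))))
    }
    if (!is.null(discordant)) {
      dp[i] <- discordant_support(discordant, cc$lost_chrom, cc$lost_start,
                                  cc$dup_chrom, cc$dup_start, window) +
        discordant_support(discordant, cc$lost_chrom, cc$lost_end,
                           cc$dup_chrom, cc$dup_end, window)
    }
    if (!is.null(contacts) || !is.null(discordant)) {
      pass_c <- !is.na(ce[i]) && ce[i] >= min_contact
      pass_p <- !is.na(dp[i]) && dp[i] >= min_pairs
      keep[i] <- pass_c || pass_p
    }
  }
  out <- candidates
  out$contact_enrichment <- ce
  out$discordant_pairs <- dp
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes lost through a homeologous exchange
#'
#' Genes inside the lost (0-copy) segment whose homeolog partner is not
#' inside the duplicated segment are gone from the genome: the replacing
#' segment carries no copy of them.
#'
#' @param call one row of a \code{\link{call_he}} result.
#' @param annotation a \code{\link{genome_annotation}}.
#' @return Character vector of lost gene ids.
#' @export
genes_lost <- function(call, annotation) {
  lost <- .genes_in_segment(annotation, call$lost_chrom, call$lost_start,
                            call$lost_end)
  dup <- .genes_in_segment(annotation, call$dup_chrom, call$dup_start,
                           call$dup_end)
  partner <- setNames(annotation$genes$partner, annotation$genes$gene_id)
  lost[is.na(partner[lost]) | !(partner[lost] %in% dup)]
}

#' End-to-end HE detection from a coverage track
#'
#' Convenience wrapper: \code{\link{window_copy_states}},
#' \code{\link{segment_states}}, \code{\link{pair_reciprocal_events}},
#' \code{\link{call_he}}.
#'
#' @param track a \code{\link{coverage_track}} spanning both subgenomes.
#' @param annotation,map reference annotation and homeolog pairs.
#' @param contacts,discordant optional orthogonal evidence.
#' @param min_run,min_jaccard,min_contact,min_pairs thresholds (see the
#'   stage functions).
#' @return An HE call table (see \code{\link{call_he}}).
#' @export
detect_he <- function(track, annotation, map, contacts = NULL,
                      discordant = NULL, min_run = 5, min_jaccard = 0.5,
                      min_contact = 2.0, min_pairs = 3) {
  states <- window_copy_states(track)
  segs <- segment_states(states, min_run = min_run)
  cand <- pair_reciprocal_events(segs, annotation, map,
                                 min_jaccard = min_jaccard)
  call_he(cand, contacts = contacts, discordant = discordant,
          min_contact = min_contact, min_pairs = min_pairs)
}
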