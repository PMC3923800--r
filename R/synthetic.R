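#' Reaction-type templates for the synthetic generator
#'
#' Six templates emulating the chemistry of common photocycloaddition
#' families.  Each template defines a hydrogen-conserving signature -- ppm
#' regions where signals are lost (reactant side) and gained (product
#' side) -- plus spectator-peak settings.  The signature regions are chosen
#' from typical 1H shift ranges: olefinic protons 5-7 ppm, aromatic ~7-8
#' ppm, heteroaromatic ~8-9 ppm, and the saturated ring protons formed by
#' cycloaddition 2-5 ppm.
#'
#' * `azirine.CC.3p2`    -- [3+2] azirine + C=C: olefinic H (5.7-6.5) to
#'   pyrroline ring H (3.3-4.1)
#' * `CC.CO.2p2`         -- [2+2] C=C + C=O: olefinic H (5.8-6.8) to
#'   oxetane O-CH (4.3-5.0)
#' * `arene.olefin.4p2`  -- [4+2]/[4+4] arene + olefin: aromatic H
#'   (6.9-7.7) and olefinic H (5.4-6.2) to bridgehead/ring CH (2.9-3.7,
#'   2.0-2.6)
#' * `CC.CC.2p2`         -- [2+2] C=C + C=C: olefinic H (5.3-6.3) to
#'   cyclobutane H (2.2-3.0)
#' * `triazolo.CC.3p2`   -- [3+2] s-triazolopyridazine + C=C:
#'   heteroaromatic H (7.7-8.7) to saturated ring H (3.7-4.5)
#' * `CC.CS.2p2`         -- [2+2] C=C + C=S: olefinic H (5.9-6.9) to
#'   thietane H (3.0-3.6)
#'
#' @param driftSd standard deviation (ppm) of the reactant-to-product
#'   drift of spectator peaks (default 0.15, comparable to typical
#'   prediction errors of empirical shift predictors).
#' @return Named list of six templates, each a list with elements `label`,
#'   `signature` (data.frame lostLo, lostHi, gainLo, gainHi, protons),
#'   `spectatorCount`, `spectatorRegion`, `protonChoices`, `driftSd`.
#' @export
reactionTemplates <- function(driftSd = 0.15) {
    sig <- function(...) {
        m <- matrix(c(...), ncol = 5, byrow = TRUE)
        data.frame(lostLo = m[, 1], lostHi = m[, 2],
                   gainLo = m[, 3], gainHi = m[, 4], protons = m[, 5])
    }
    labels <- c("azirine.CC.3p2", "CC.CO.2p2", "arene.olefin.4p2",
                "CC.CC.2p2", "triazolo.CC.3p2", "CC.CS.2p2")
    sigs <- list(
        sig(5.7, 6.5, 3.3, 4.1, 2),
        sig(5.8, 6.8, 4.3, 5.0, 2),
        sig(6.9, 7.7, 2.9, 3.7, 2,
            5.4, 6.2, 2.0, 2.6, 2),
        sig(5.3, 6.3, 2.2, 3.0, 2,
            5.3, 6.3, 2.2, 3.0, 2),
        sig(7.7, 8.7, 3.7, 4.5, 2),
        sig(5.9, 6.9, 3.0, 3.6, 2))
    out <- Map(function(lab, s) list(
        label = lab, signature = s,
        spectatorCount = c(3L, 10L), spectatorRegion = c(0.5, 9.5),
        protonChoices = 1:3, driftSd = driftSd), labels, sigs)
    names(out) <- labels
    out
}

#' Sample one synthetic reaction from a template
#'
#' Reactant peaks are the signature's lost shifts (positions drawn
#' uniformly inside each lost region) plus a random number of spectator
#' peaks; product peaks are the signature's gained shifts (drawn in the
#' gained regions) plus the same spectators displaced by
#' `Normal(0, driftSd)` -- spectators nearly cancel in the difference
#' spectrum, leaving small residuals that emulate shift-prediction error.
#' The total proton count is conserved exactly.  Signature lost peaks and
#' spectators are split over two reactant spectra.
#'
#' @param template one element of [reactionTemplates()].
#' @param id identifier for the new record.
#' @return A [ReactionRecord-class].
#' @export
sampleReaction <- function(template, id = "R1") {
    s <- template$signature
    nSig <- nrow(s)
    lostShift <- if (nSig) stats::runif(nSig, s$lostLo, s$lostHi) else numeric(0)
    gainShift <- if (nSig) stats::runif(nSig, s$gainLo, s$gainHi) else numeric(0)
    nSpec <- sample(seq(template$spectatorCount[1], template$spectatorCount[2]),
                    1L)
    specShift <- stats::runif(nSpec, template$spectatorRegion[1],
                              template$spectatorRegion[2])
    specProtons <- sample(template$protonChoices, nSpec, replace = TRUE)
    drift <- stats::rnorm(nSpec, 0, template$driftSd)
    # split lost peaks and spectators over the two reactants
    sigTo1 <- if (nSig) seq_len(nSig) %% 2L == 1L else logical(0)
    specTo1 <- seq_len(nSpec) %% 2L == 1L
    r1 <- ShiftList(c(lostShift[sigTo1], specShift[specTo1]),
                    c(s$protons[sigTo1], specProtons[specTo1]))
    r2 <- ShiftList(c(lostShift[!sigTo1], specShift[!specTo1]),
                    c(s$protons[!sigTo1], specProtons[!specTo1]))
    product <- ShiftList(c(gainShift, specShift + drift),
                         c(s$protons, specProtons))
    ReactionRecord(id, template$label, list(r1, r2), product)
}

#' Generate a synthetic reaction dataset
#'
#' Draws `counts[k]` reactions from the k-th template.  The default counts
#' (20, 31, 20, 73, 10, 27; total 181) match the per-type composition of
#' the photocycloaddition benchmark this generator emulates.
#'
#' @param counts integer vector of per-type reaction counts, one per
#'   template.
#' @param seed integer seed (NULL: current RNG stream).
#' @param driftSd spectator drift standard deviation in ppm.
#' @param templates template list (default [reactionTemplates()]).
#' @return A [ReactionSet-class] whose type registry follows the template
#'   order.
#' @export
generateReactions <- function(counts = c(20, 31, 20, 73, 10, 27),
                              seed = NULL, driftSd = 0.15,
                              templates = reactionTemplates(driftSd)) {
    stopifnot(length(counts) == length(templates), all(counts >= 0))
    .withSeed(seed, {
        recs <- list()
        for (k in seq_along(templates)) {
            for (i in seq_len(counts[k])) {
                recs[[length(recs) + 1L]] <- sampleReaction(
                    templates[[k]],
                    id = sprintf("R%03d", length(recs) + 1L))
            }
        }
        ReactionSet(recs, typeLevels = vapply(templates, `[[`,
                                              character(1), "label"))
    })
}
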