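# Compact two-amplicon fixture panel built in code: AMP1 carries one marker,
# AMP2 carries two (mirroring the two TERT promoter sites on one amplicon).
# Short amplicons keep the property tests fast; junction-adjacent bases are
# kept distinct from both alleles, as in the shipped panel.
make_test_panel <- function(flank = 10L) {
  ampliSNV:::with_preserved_seed(4242, {
    mk_spec <- list(
      AMP1 = list(len = 160L, sites = list(list("M1", 80L, "G", c(mutA = "A")))),
      AMP2 = list(len = 180L, sites = list(list("M2a", 70L, "C", c(mutT = "T")),
                                           list("M2b", 92L, "A", c(mutG = "G"))))
    )
    amps <- list(); mks <- list()
    for (aid in names(mk_spec)) {
      sp <- mk_spec[[aid]]
      bases <- sample(c("A", "C", "G", "T"), sp$len, replace = TRUE)
      for (s in sp$sites) {
        off <- s[[2]]; wt <- s[[3]]; muts <- s[[4]]
        bases[off + 1L] <- wt
        ctx <- setdiff(c("A", "C", "G", "T"), c(wt, muts))
        for (d in c(-2L, -1L, 1L, 2L)) bases[off + 1L + d] <- sample(ctx, 1L)
        mks[[length(mks) + 1L]] <- marker_site(s[[1]], aid, off, 1L, wt, muts)
      }
      amps[[length(amps) + 1L]] <- amplicon(aid, paste(bases, collapse = ""),
                                            "test fixture amplicon")
    }
    panel(amps, mks, flank = flank)
  })
}

# weights putting all mass on one amplicon
solo_weights <- function(panel, amplicon_id) {
  w <- amplicon_weights(panel)
  w[] <- 0
  w[amplicon_id] <- 1
  w
}
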