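# Scripted NOVEL-like fixture: 90 acquisition trials (round-robin, always
# choose left), reversal at trial 91, then 30 hand-written PoE trials that
# encode the worked positive (5-vs-2 unchosen, 5-vs-3 chosen, 1-vs-5
# evaluated) and negative (1-vs-2 unchosen, 1-vs-4 chosen, 1-vs-3 evaluated)
# experience chains. Under pattern B: S1=5, S2=4, S3=3, S4=2, S5=1 drops.
experience_fixture <- function() {
  base_pairs <- list(c("S1", "S2"), c("S1", "S3"), c("S1", "S4"), c("S1", "S5"),
                     c("S2", "S3"), c("S2", "S4"), c("S2", "S5"), c("S3", "S4"),
                     c("S3", "S5"), c("S4", "S5"))
  acq_pairs <- rep(base_pairs, 9)
  acq_choices <- vapply(acq_pairs, `[`, "", 1)
  poe <- list(
    list(c("S2", "S3"), "S2"),  # 91
    list(c("S3", "S4"), "S4"),  # 92
    list(c("S1", "S4"), "S4"),  # 93  S1 (5 drops) offered vs 2, not chosen
    list(c("S2", "S3"), "S2"),  # 94
    list(c("S3", "S4"), "S4"),  # 95
    list(c("S3", "S1"), "S1"),  # 96  S1 chosen vs 3 -> positive event
    list(c("S2", "S3"), "S2"),  # 97
    list(c("S3", "S4"), "S4"),  # 98
    list(c("S5", "S1"), "S1"),  # 99  1-vs-5: evaluation trial for S1
    list(c("S2", "S3"), "S2"),  # 100
    list(c("S5", "S4"), "S4"),  # 101 S5 (1 drop) offered vs 2, not chosen
    list(c("S2", "S3"), "S2"),  # 102
    list(c("S3", "S4"), "S4"),  # 103
    list(c("S5", "S2"), "S5"),  # 104 1-vs-4, chose 1 -> negative event
    list(c("S2", "S3"), "S2"),  # 105 also S2's positive event (unchosen at 104)
    list(c("S3", "S4"), "S4"),  # 106
    list(c("S5", "S3"), "S3"),  # 107 1-vs-3: evaluation trial for S5
    list(c("S2", "S3"), "S2"),  # 108 evaluation trial for S2
    list(c("S3", "S4"), "S4"),  # 109
    list(c("S2", "S3"), "S2"),  # 110
    list(c("S3", "S4"), "S4"),  # 111
    list(c("S2", "S3"), "S2"),  # 112
    list(c("S3", "S4"), "S4"),  # 113
    list(c("S2", "S3"), "S2"),  # 114
    list(c("S3", "S4"), "S4"),  # 115
    list(c("S2", "S3"), "S2"),  # 116
    list(c("S3", "S4"), "S4"),  # 117
    list(c("S2", "S3"), "S2"),  # 118
    list(c("S3", "S4"), "S4"),  # 119
    list(c("S2", "S3"), "S2")   # 120
  )
  make_session(c(acq_pairs, lapply(poe, `[[`, 1)),
               c(acq_choices, vapply(poe, `[[`, 2, FUN.VALUE = "")),
               task = "NOVEL", boundary_at = 91, session_id = "events-1")
}
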