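# shared assay fixtures with hand-computed expected values

mk_ct <- function(sample, group, target_ct, ref_ct) {
  rbind(data.frame(sample = sample, group = group, gene = "TEAD1",
                   role = "target", ct = target_ct),
        data.frame(sample = sample, group = group, gene = "U6",
                   role = "reference", ct = ref_ct))
}

# hand-computed relative-quantification table (spreadsheet oracle):
# calibrator samples c1 (dCt 4.2) and c2 (dCt 4.6), mean 4.4;
# treatment samples t1 (dCt 2.0) and t2 (dCt 3.0)
ddct_fixture <- rbind(
  mk_ct("c1", "cal", c(24.0, 24.2, 24.4), c(20.0, 20.0, 20.0)),
  mk_ct("c2", "cal", c(24.6, 24.8, 25.0), c(20.4, 20.2, 20.0)),
  mk_ct("t1", "trt", c(22.0, 22.0, 22.0), c(20.0, 20.1, 19.9)),
  mk_ct("t2", "trt", c(23.0, 23.2, 23.1), c(20.1, 20.1, 20.1)))

luc_fixture <- data.frame(
  construct = rep(c("WT", "MT"), each = 6),
  treatment = rep(rep(c("NC", "mimic"), each = 3), 2),
  hluc = c(2.0, 2.2, 1.8, 1.0, 1.1, 0.9,   # WT: mimic halves the ratio
           1.5, 1.5, 1.5, 1.5, 1.5, 1.5),  # MT: unchanged
  hrluc = 1)
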