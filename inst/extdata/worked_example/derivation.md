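# Worked example: hand derivation

The `worked_example()` cohort is built from explicit deterministic values so
the whole screen can be traced by hand. Two cancers (A, B) with 20 samples
each, 10 features of mature length 1,000 bp, one driver event (`DRIVER1`).

## Construction

- Within-cancer sample index `j = 1..20`; null features `F01..F09` have
  FPKM `b_i + 0.01 j` with `b_i = i`.
- Mutated samples: cancer A `j ∈ {1,4,7,10,13,16}`, cancer B
  `j ∈ {2,5,8,11,14,17}` (6 of 20 per cancer), recorded as
  `Missense_Mutation` in the MAF. Sample `A_S18` carries only a `Silent`
  record of `DRIVER1` and therefore stays wild type under the mutation-class
  rule (missense/nonsense/indel/splice-site qualify; silent does not).
- `F01` is additionally induced 8-fold in the mutated samples.
- `F10` has FPKM 0 in every mutated sample and `0.5 + 0.01 j` otherwise.
- Counts invert the FPKM formula at equal library sizes:
  `counts = round(FPKM * 100)`, which is exact here
  (`100 b_i + j`, and `800 b_1 + 8 j` for mutated `F01`).

Re-quantifying the counts through median-of-ratios size factors changes
each sample's FPKM by a common per-sample factor (size factors fall in
[0.98, 1.02] on this cohort), so within-feature sample ranks — and hence
every rank-sum p-value below — are unchanged.

## Rank-sum arithmetic for F01 in cancer A

All six mutated values (≈ 8.1–8.5 after normalization) exceed all fourteen
wild-type values (≈ 1.07–1.20), so the mutated samples occupy the top six
ranks:

- rank sum `W = 15 + 16 + 17 + 18 + 19 + 20 = 105`
- `n1 = 6`, `n2 = 14`, `N = 20`; `mu = n1 (N + 1) / 2 = 63`
- no ties: `var = n1 n2 (N + 1) / 12 = 147`
- `z = (|W - mu| - 0.5) / sqrt(var) = 41.5 / 12.124356 = 3.4228623`
- two-sided `p = 2 Φ(−z) = 6.1965457e-4 < 0.001`

The same pattern holds in cancer B (mutated ranks 15–20, identical p).

Log2 ratio in cancer A (pipeline FPKM, pseudo-count 0.1):
`log2((mean_mut + 0.1) / (mean_wt + 0.1)) = 2.9677771` (B: 2.9829254),
comfortably above the two-fold threshold. F01 therefore passes in both
cancers with direction "up": **exactly one consistent association**.

## Null and filter behaviour

- `F02` (null pattern) in cancer A: mutated ranks are {1,4,7,10,13,16},
  `W = 51`, `z = (|51 − 63| − 0.5)/12.124356 = 0.9485`, `p = 0.3429` —
  far from passing. Every null feature shares this rank pattern.
- `F10` separates the groups perfectly but has 0/6 nonzero mutated values,
  failing the 10% detectability requirement in the mutated group:
  `detectable = FALSE`, `passes = FALSE` regardless of its p-value.
- Permuting mutation labels within each cancer (seed 20260922) yields 0
  consistent associations.

`screen_golden.tsv` and `consistent_golden.tsv` are the frozen outputs of
the screen on this cohort; re-running the pipeline must reproduce them
byte-identically.
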