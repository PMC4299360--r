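id	description
t1_v2_row_alignment	The published anterior-V2 row of the COW cross-tabulation prints only five values (2, 4, 2, 2, 1) with ambiguous column alignment; table1.tsv allocates them to columns d, e, f, g, j. With that allocation every column sum of table1.tsv equals the posterior count vector of table5.tsv exactly and the missing V1 x k cell is 0. The allocation is documented data, not a classification rule.
anterior_integral_posterior_nonintegral_count	The source reports both 1489 and 1490 for subjects with integral anterior but nonintegral posterior circulation; the table1.tsv reconstruction yields 1490. Recorded, not resolved.
a1_variation_rate_rounding	The A1-variation rate is reported both as 28.18% and 28.23%; 634/2246 = 28.228%, so the count-derived value rounds to 28.23.
z_p1_sides	The published rank-sum Z for the left/right PCA-P1 status distributions is 2.576 with p = 0.01; the tie-corrected normal-approximation rank-sum (the convention that reproduces Z = 9.944 exactly on the A1 data) gives Z = 2.4668, p = 0.0136. 2.5758 equals the two-sided normal quantile for p = 0.01, so the published Z appears back-derived from the rounded p-value. The package reports the computed value.
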