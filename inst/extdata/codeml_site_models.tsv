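# Reported codeml site-model estimates for five A. trichopoda LRR-RLK
# subfamilies: M0 omega and log-likelihood, M1 (nearly neutral) omega0/p0
# and log-likelihood, M3 (discrete) log-likelihood, and the reported
# 2|dlnL| statistic of the M0-vs-M3 likelihood-ratio test.
# NOTE: the originally reported M0 log-likelihood for subfamily I
# (-11330.92) is inconsistent with that subfamily's own reported M3
# log-likelihood and M0-vs-M3 statistic; the value below (-6389.67) is
# reconstructed from those two mutually consistent numbers
# (m3_lnl - lrt_m3_m0 / 2) and is flagged in m0_lnl_reconstructed.
subfamily	m0_omega	m0_lnl	m0_lnl_reconstructed	m1_omega0	m1_p0	m1_lnl	m3_lnl	lrt_m3_m0
I	0.3743	-6389.67	TRUE	0.1112	0.561	-6245.62	-6236.24	306.86551
II	0.0920	-11063.62	FALSE	0.0807	0.738	-10906.03	-10795.06	537.108832
III	0.2292	-40462.98	FALSE	0.1643	0.379	-39806.09	-39489.33	1947.3058
VIII-1	0.2949	-11381.07	FALSE	0.0727	0.532	-11239.85	-11218.68	324.776964
XII	0.2182	-23228.48	FALSE	0.1336	0.530	-22876.97	-22754.11	948.721848
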