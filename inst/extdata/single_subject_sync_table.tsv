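network	plv_mean	plv_sd	mismatched_mean	mismatched_sd	p_uncorrected	p_fdr	fractional_gastric_variance
AUD1	0.1882	0.1056	0.1709	0.0935	0.1852	0.2578	0.0111
AUD2	0.1995	0.1040	0.1725	0.0860	0.0439	0.0987	0.0266
AUD3	0.1791	0.0806	0.1567	0.0808	0.0330	0.0944	0.0064
SMOT_ven	0.1854	0.0941	0.1729	0.0891	0.1862	0.2578	0.0038
SMOT_dor1	0.2061	0.0758	0.1697	0.0845	0.0029	0.0227	0.0150
SMOT_dor2	0.1947	0.0855	0.1705	0.0855	0.0367	0.0944	0.0057
VIS_a	0.1939	0.1078	0.1711	0.0815	0.1619	0.2578	0.0338
VIS_b	0.1978	0.1288	0.1775	0.0911	0.3636	0.4090	0.0420
DMN_a	0.1746	0.0882	0.1719	0.0892	0.4351	0.4607	0.0242
DMN_b	0.1990	0.0857	0.1612	0.0856	0.0038	0.0227	0.0291
DMN_c	0.1987	0.1085	0.1639	0.0849	0.0346	0.0944	0.0185
ATTN_ven1	0.1860	0.1078	0.1705	0.0920	0.1504	0.2578	0.0071
ATTN_ven2	0.1920	0.0812	0.1651	0.0845	0.0178	0.0802	0.0139
ATTN_dor	0.1620	0.0804	0.1634	0.0834	0.4773	0.4773	0.0201
EXEC_r	0.1797	0.0996	0.1645	0.0822	0.2523	0.3159	0.0071
EXEC_l	0.1689	0.0885	0.1603	0.0854	0.2633	0.3159	0.0079
SAL	0.1952	0.0831	0.1785	0.0902	0.0923	0.1846	0.0095
CB	0.2093	0.1002	0.1539	0.0791	0.0001	0.0022	0.1124
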