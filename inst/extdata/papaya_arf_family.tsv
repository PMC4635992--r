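name	gene_id	location	direction	orf_len	introns	length_aa	mol_wt_kda	pi
CpARF1	evm.TU.supercontig_9.161	supercontig_9:969763..974848	Reverse	2094	13	698	77.67	7.18
CpARF2	evm.TU.contig_31756.1	contig_31756:3939..7439	Forward	1855	11	619	68.86	7.12
CpARF3	evm.TU.supercontig_7.3	supercontig_7:132322..138926	Reverse	2022	10	674	73.19	7.01
CpARF4	evm.TU.supercontig_139.80	supercontig_139:638531..645762	Reverse	2439	11	813	89.78	6.58
CpARF5	evm.TU.supercontig_26.24	supercontig_26:231561..267729	Reverse	2814	13	938	103.7	5.16
CpARF6	evm.TU.supercontig_17.53	supercontig_17:617715..620541	Reverse	933	8	311	34.83	9.03
CpARF7	evm.TU.supercontig_261.2	supercontig_261:2520..11208	Reverse	2649	12	883	97.65	5.52
CpARF10	evm.TU.supercontig_65.4	supercontig_65:11160..14085	Reverse	1944	4	648	71.54	7.06
CpARF11	evm.TU.supercontig_96.40	supercontig_96:684489..688508	Forward	2064	13	688	76.05	6.66
CpARF16	evm.TU.supercontig_53.88	supercontig_53:584129..586644	Reverse	2091	2	697	76.94	6.57
CpARF17	evm.TU.supercontig_49.122	supercontig_49:862531..867248	Reverse	1809	1	603	66.22	6.51
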