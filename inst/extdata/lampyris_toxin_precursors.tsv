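name	protein	signal_end	cleavage_pos	printed_mh	tpm
U-Lampyristoxin-Ln1a	MKLSTFVLVTIMFVLLCAVQAEPVVERANCGLCPVFCKLGFHCTANGQRCC	21	27	2539.01/3248.4	18044
U-Lampyristoxin-Ln1b	MKLSTFVLVTIMFGFLCAVQAAQVVVRANCDLCAPFCAAGFHCTANGQRCC	21	27	2469.89/3122.27	13146
U-Lampyristoxin-Ln1c	MKLTFVLVTIMFVLLCAVRADPAVMVRANCDLCKPFCAVGIHCTANGESCC	22	27	2452.91/3009.22	8310
U-Lampyristoxin-Ln2	MNRSIFILLLVISVLFAAVVAVPIHEKEELPHLMLYTRAVSCKAVSSRPNDPSSYNEACNAHCILNGNRGGVCGSGTCICLG	21	38	4378.8	7326
U-Lampyristoxin-Ln3	MFSSLLLICLLPILVLGTGTSGPVDFHPEEPCNRAGGQCIKRDECPVHIEDIYLNLCPQQQSQGAECCHGISTKEYRCKKFGGECFREGSKCPDNLKRPQATDCPAGKFCCVLI	17	NA	10661.77	2
U-Lampyristoxin-Ln4	MKWLLCFVIACALRVYSKRINVGALVPERECLKDYRDNFPKIIYALYSISPSNDEVVGEYFICTLKKRQILEDNGEINPEKIYKYWVEVYQTTIISPSEEKEISDAAEECAKLKDDKMAFLALKIKNCILEGAHKLPFVG	17	29	12803.47	56
U-Lampyristoxin-Ln5a	MVILAIFGRVDAADVSLGCTLSCSIWNACRVKAALSGNLESCGPQPGGCRCTQFAWER	12	NA	4839.16	6
U-Lampyristoxin-Ln5b	MKNIVLLSVLAMVILAIFGRVDSADISWGCTLSCSIWNACRVKAALSGNLKSCDPQPEGCRCTQFAWER	23	NA	5055.25	18
U-Lampyristoxin-Ln6	MNRTLVIFLVFIFGFVIAESMVVQGGDRYKYCRIAQCKIDCVFQNHIDGFCKNNQCVCTDYN	22	NA	4656.00	19
U-Lampyristoxin-Ln7	MVRVVIYTTILALMLFNVMAGPLLNEDQAQLIRHKRASCSSVTTNGDSRGGWANEGCRAYCVMSGYRTGLCSQGTCACR	20	NA	6288.81	76
NLVC 1	MKLIIFLLVVCMVFAVPISSYCYFCADQCNPGETTYPDSDCPPGKVSCCKA	20	NA	3359.22	1
NLVC 2	MKTFLVVLLITILYMSLSVDADCGERCQFMPCRTGYTGVPERCPGGGIRCCPP	21	NA	3439.38	104
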