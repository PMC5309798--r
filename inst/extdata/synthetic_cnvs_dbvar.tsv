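id	chrom	start	end	type	interpretation	study
cnv_b_gain_0006	1	126002	131292	gain	benign	synthetic
cnv_p_gain_0005	1	567803	842612	gain	pathogenic	synthetic
cnv_b_gain_0009	1	880983	885011	gain	benign	synthetic
cnv_b_loss_0012	1	929547	956358	loss	benign	synthetic
cnv_b_loss_0010	1	1105025	1112661	loss	benign	synthetic
cnv_p_loss_0001	1	1877998	2050180	loss	pathogenic	synthetic
cnv_b_gain_0008	1	2205084	2222076	gain	benign	synthetic
cnv_p_gain_0003	1	2258541	2377583	gain	pathogenic	synthetic
cnv_b_gain_0002	1	2411652	2432036	gain	benign	synthetic
cnv_b_gain_0010	1	2496316	2504991	gain	benign	synthetic
cnv_b_gain_0007	1	3270551	3320560	gain	benign	synthetic
cnv_p_loss_0006	1	3366858	3627564	loss	pathogenic	synthetic
cnv_p_gain_0008	1	3861240	4111084	gain	pathogenic	synthetic
cnv_p_loss_0007	1	4008961	4322893	loss	pathogenic	synthetic
cnv_p_loss_0004	1	4494220	4637441	loss	pathogenic	synthetic
cnv_b_loss_0002	1	4543508	4557756	loss	benign	synthetic
cnv_b_loss_0005	1	4557793	4795244	loss	benign	synthetic
cnv_b_gain_0003	1	4700215	4703360	gain	benign	synthetic
cnv_b_gain_0005	1	4767553	4773583	gain	benign	synthetic
cnv_b_loss_0004	2	617727	671040	loss	benign	synthetic
cnv_b_gain_0011	2	742896	771617	gain	benign	synthetic
cnv_p_loss_0005	2	923484	1153884	loss	pathogenic	synthetic
cnv_p_loss_0008	2	1027589	1155767	loss	pathogenic	synthetic
cnv_b_loss_0001	2	1438505	1455294	loss	benign	synthetic
cnv_b_loss_0006	2	1510508	1522078	loss	benign	synthetic
cnv_b_gain_0001	2	1860674	1899134	gain	benign	synthetic
cnv_b_loss_0007	2	1976156	1992337	loss	benign	synthetic
cnv_p_gain_0001	2	2592204	2823881	gain	pathogenic	synthetic
cnv_p_gain_0007	2	2705772	2852467	gain	pathogenic	synthetic
cnv_p_loss_0002	2	2802006	3077004	loss	pathogenic	synthetic
cnv_b_gain_0004	2	3001969	3019481	gain	benign	synthetic
cnv_b_loss_0008	2	3281797	3294224	loss	benign	synthetic
cnv_p_gain_0006	2	3463065	3598974	gain	pathogenic	synthetic
cnv_b_loss_0009	2	3611460	3750454	loss	benign	synthetic
cnv_p_loss_0003	2	3780212	3889024	loss	pathogenic	synthetic
cnv_p_gain_0002	2	3915691	3955576	gain	pathogenic	synthetic
cnv_b_loss_0011	2	3944046	3945480	loss	benign	synthetic
cnv_p_gain_0004	2	4413574	4695778	gain	pathogenic	synthetic
cnv_b_loss_0003	2	4837917	4855543	loss	benign	synthetic
cnv_b_gain_0012	2	4892469	4906936	gain	benign	synthetic
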