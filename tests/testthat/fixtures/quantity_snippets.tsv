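text	kind	quantity	unit
输注悬浮少白红细胞2U	transfusion_rbc	2	U
输注悬浮少白红细胞4U	transfusion_rbc	4	U
予输注悬浮少白红细胞1U	transfusion_rbc	1	U
输悬浮红细胞3U	transfusion_rbc	3	U
给予2单位红细胞悬液	transfusion_rbc	2	U
给予三单位红细胞悬液	transfusion_rbc	3	U
输注红细胞悬液2单位	transfusion_rbc	2	U
予输注全血1U	transfusion_rbc	1	U
输注悬浮少白红细胞两U	transfusion_rbc	2	U
今日输注悬浮少白红细胞2U，过程顺利	transfusion_rbc	2	U
给予1单位悬浮红细胞	transfusion_rbc	1	U
输红悬2U	transfusion_rbc	2	U
术后予输注少白悬浮红细胞2U	transfusion_rbc	2	U
急诊输注红细胞4单位	transfusion_rbc	4	U
输注全血2U	transfusion_rbc	2	U
输注悬浮少白红细胞400ml	transfusion_rbc	400	mL
予输红细胞悬液300ml	transfusion_rbc	300	mL
给予400ml悬浮红细胞	transfusion_rbc	400	mL
输注全血200ml	transfusion_rbc	200	mL
输悬浮少白红细胞150ml	transfusion_rbc	150	mL
出血约300ml	blood_loss	300	mL
失血200ml	blood_loss	200	mL
术中出血约1000ml	blood_loss	1000	mL
出血量约50ml	blood_loss	50	mL
血性渗出约20ml	blood_loss	20	mL
术中失血约800ml	blood_loss	800	mL
出血100ml	blood_loss	100	mL
出血约10ml	blood_loss	10	mL
皮下瘀斑，出血约30ml	blood_loss	30	mL
创面出血约250ml	blood_loss	250	mL
引流出暗红色液体300ml	drainage	300	mL
引流液约150ml	drainage	150	mL
腹腔引流200ml	drainage	200	mL
引出血性液体100ml	drainage	100	mL
盆腔引流约80ml	drainage	80	mL
引流管引流出淡黄液体40ml	drainage	40	mL
术后引流约60ml	drainage	60	mL
引流出血性液体约350ml	drainage	350	mL
无出血	none
病情平稳，生命体征正常	none
输液500ml	none
体温36.8度	none
无明显出血及渗液	none
伤口干燥，愈合良好	none
血红蛋白110g/l	none
继续补液治疗	none
术后第3日查房	none
既往无出血性疾病史	none
嘱定期复查血常规	none
切口少量渗血	none
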