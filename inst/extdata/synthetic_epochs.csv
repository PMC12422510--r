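timestamp,counts
2012-03-05 12:00:00,1601
2012-03-05 12:01:00,548
2012-03-05 12:02:00,699
2012-03-05 12:03:00,1278
2012-03-05 12:04:00,912
2012-03-05 12:05:00,104
2012-03-05 12:06:00,1761
2012-03-05 12:07:00,1022
2012-03-05 12:08:00,1052
2012-03-05 12:09:00,1034
2012-03-05 12:10:00,783
2012-03-05 12:11:00,1948
2012-03-05 12:12:00,397
2012-03-05 12:13:00,202
2012-03-05 12:14:00,34
2012-03-05 12:15:00,1384
2012-03-05 12:16:00,237
2012-03-05 12:17:00,1875
2012-03-05 12:18:00,1450
2012-03-05 12:19:00,1465
2012-03-05 12:20:00,1110
2012-03-05 12:21:00,699
2012-03-05 12:22:00,1915
2012-03-05 12:23:00,1923
2012-03-05 12:24:00,1670
2012-03-05 12:25:00,1012
2012-03-05 12:26:00,211
2012-03-05 12:27:00,1858
2012-03-05 12:28:00,1304
2012-03-05 12:29:00,289
2012-03-05 12:30:00,1240
2012-03-05 12:31:00,1848
2012-03-05 12:32:00,816
2012-03-05 12:33:00,944
2012-03-05 12:34:00,152
2012-03-05 12:35:00,704
2012-03-05 12:36:00,2053
2012-03-05 12:37:00,1742
2012-03-05 12:38:00,716
2012-03-05 12:39:00,463
2012-03-05 12:40:00,426
2012-03-05 12:41:00,1377
2012-03-05 12:42:00,2233
2012-03-05 12:43:00,2155
2012-03-05 12:44:00,260
2012-03-05 12:45:00,1154
2012-03-05 12:46:00,152
2012-03-05 12:47:00,2236
2012-03-05 12:48:00,258
2012-03-05 12:49:00,444
2012-03-05 12:50:00,527
2012-03-05 12:51:00,2256
2012-03-05 12:52:00,1991
2012-03-05 12:53:00,584
2012-03-05 12:54:00,787
2012-03-05 12:55:00,1775
2012-03-05 12:56:00,117
2012-03-05 12:57:00,874
2012-03-05 12:58:00,146
2012-03-05 12:59:00,1675
2012-03-05 13:00:00,0
2012-03-05 13:01:00,0
2012-03-05 13:02:00,0
2012-03-05 13:03:00,0
2012-03-05 13:04:00,0
2012-03-05 13:05:00,0
2012-03-05 13:06:00,0
2012-03-05 13:07:00,0
2012-03-05 13:08:00,0
2012-03-05 13:09:00,0
2012-03-05 13:10:00,0
2012-03-05 13:11:00,0
2012-03-05 13:12:00,0
2012-03-05 13:13:00,0
2012-03-05 13:14:00,0
2012-03-05 13:15:00,0
2012-03-05 13:16:00,0
2012-03-05 13:17:00,0
2012-03-05 13:18:00,0
2012-03-05 13:19:00,0
2012-03-05 13:20:00,0
2012-03-05 13:21:00,0
2012-03-05 13:22:00,0
2012-03-05 13:23:00,0
2012-03-05 13:24:00,0
2012-03-05 13:25:00,0
2012-03-05 13:26:00,0
2012-03-05 13:27:00,0
2012-03-05 13:28:00,0
2012-03-05 13:29:00,0
2012-03-05 13:30:00,0
2012-03-05 13:31:00,0
2012-03-05 13:32:00,0
2012-03-05 13:33:00,0
2012-03-05 13:34:00,0
2012-03-05 13:35:00,0
2012-03-05 13:36:00,0
2012-03-05 13:37:00,0
2012-03-05 13:38:00,0
2012-03-05 13:39:00,0
2012-03-05 13:40:00,0
2012-03-05 13:41:00,0
2012-03-05 13:42:00,0
2012-03-05 13:43:00,0
2012-03-05 13:44:00,0
2012-03-05 13:45:00,0
2012-03-05 13:46:00,0
2012-03-05 13:47:00,0
2012-03-05 13:48:00,0
2012-03-05 13:49:00,0
2012-03-05 13:50:00,0
2012-03-05 13:51:00,0
2012-03-05 13:52:00,0
2012-03-05 13:53:00,0
2012-03-05 13:54:00,0
2012-03-05 13:55:00,0
2012-03-05 13:56:00,0
2012-03-05 13:57:00,0
2012-03-05 13:58:00,0
2012-03-05 13:59:00,0
2012-03-05 14:00:00,0
2012-03-05 14:01:00,0
2012-03-05 14:02:00,0
2012-03-05 14:03:00,0
2012-03-05 14:04:00,0
2012-03-05 14:05:00,0
2012-03-05 14:06:00,0
2012-03-05 14:07:00,0
2012-03-05 14:08:00,0
2012-03-05 14:09:00,0
2012-03-05 14:10:00,0
2012-03-05 14:11:00,0
2012-03-05 14:12:00,0
2012-03-05 14:13:00,0
2012-03-05 14:14:00,0
2012-03-05 14:15:00,0
2012-03-05 14:16:00,0
2012-03-05 14:17:00,0
2012-03-05 14:18:00,0
2012-03-05 14:19:00,0
2012-03-05 14:20:00,0
2012-03-05 14:21:00,0
2012-03-05 14:22:00,0
2012-03-05 14:23:00,0
2012-03-05 14:24:00,0
2012-03-05 14:25:00,0
2012-03-05 14:26:00,0
2012-03-05 14:27:00,0
2012-03-05 14:28:00,0
2012-03-05 14:29:00,0
2012-03-05 14:30:00,4295
2012-03-05 14:31:00,4152
2012-03-05 14:32:00,4191
2012-03-05 14:33:00,5126
2012-03-05 14:34:00,5539
2012-03-05 14:35:00,2996
2012-03-05 14:36:00,2748
2012-03-05 14:37:00,2362
2012-03-05 14:38:00,5909
2012-03-05 14:39:00,3431
2012-03-05 14:40:00,3318
2012-03-05 14:41:00,2757
2012-03-05 14:42:00,3121
2012-03-05 14:43:00,3030
2012-03-05 14:44:00,3229
2012-03-05 14:45:00,3801
2012-03-05 14:46:00,2929
2012-03-05 14:47:00,3119
2012-03-05 14:48:00,5870
2012-03-05 14:49:00,2362
2012-03-05 14:50:00,38
2012-03-05 14:51:00,93
2012-03-05 14:52:00,61
2012-03-05 14:53:00,42
2012-03-05 14:54:00,13
2012-03-05 14:55:00,74
2012-03-05 14:56:00,72
2012-03-05 14:57:00,20
2012-03-05 14:58:00,46
2012-03-05 14:59:00,65
2012-03-05 15:00:00,9
2012-03-05 15:01:00,18
2012-03-05 15:02:00,89
2012-03-05 15:03:00,33
2012-03-05 15:04:00,58
2012-03-05 15:05:00,65
2012-03-05 15:06:00,26
2012-03-05 15:07:00,84
2012-03-05 15:08:00,93
2012-03-05 15:09:00,96
2012-03-05 15:10:00,1
2012-03-05 15:11:00,98
2012-03-05 15:12:00,36
2012-03-05 15:13:00,57
2012-03-05 15:14:00,36
2012-03-05 15:15:00,91
2012-03-05 15:16:00,84
2012-03-05 15:17:00,33
2012-03-05 15:18:00,55
2012-03-05 15:19:00,20
2012-03-05 15:20:00,35
2012-03-05 15:21:00,63
2012-03-05 15:22:00,79
2012-03-05 15:23:00,30
2012-03-05 15:24:00,40
2012-03-05 15:25:00,21
2012-03-05 15:26:00,20
2012-03-05 15:27:00,17
2012-03-05 15:28:00,1
2012-03-05 15:29:00,12
2012-03-05 15:30:00,73
2012-03-05 15:31:00,64
2012-03-05 15:32:00,50
2012-03-05 15:33:00,96
2012-03-05 15:34:00,49
2012-03-05 15:35:00,56
2012-03-05 15:36:00,0
2012-03-05 15:37:00,39
2012-03-05 15:38:00,7
2012-03-05 15:39:00,15
2012-03-05 15:40:00,4
2012-03-05 15:41:00,68
2012-03-05 15:42:00,10
2012-03-05 15:43:00,38
2012-03-05 15:44:00,0
2012-03-05 15:45:00,2
2012-03-05 15:46:00,77
2012-03-05 15:47:00,23
2012-03-05 15:48:00,87
2012-03-05 15:49:00,8
2012-03-05 15:50:00,91
2012-03-05 15:51:00,63
2012-03-05 15:52:00,28
2012-03-05 15:53:00,59
2012-03-05 15:54:00,3
2012-03-05 15:55:00,25
2012-03-05 15:56:00,43
2012-03-05 15:57:00,35
2012-03-05 15:58:00,18
2012-03-05 15:59:00,23
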